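# Independent oracles used to check the package's implementations.

# Full-matrix dynamic-programming Damerau-Levenshtein distance
# (optimal-string-alignment), written in plain R independently of the
# package's banded C++ routine.
dl_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (av[i] == bv[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + cost)
      if (i > 1 && j > 1 && av[i] == bv[j - 1] && av[i - 1] == bv[j]) {
        d[i + 1, j + 1] <- min(d[i + 1, j + 1], d[i - 1, j - 1] + 1L)
      }
    }
  }
  d[n + 1, m + 1]
}

# Nested-loop inner-join oracle over the six verbatim fields: for each
# occurrence, scan every name and compare the six fields directly.
join_oracle <- function(names_tbl, occurrences) {
  fields <- c("scientificName", "genus", "subgenus", "specificEpithet",
              "infraspecificEpithet", "scientificNameAuthorship")
  pairs <- list()
  for (i in seq_len(nrow(occurrences))) {
    for (j in seq_len(nrow(names_tbl))) {
      same <- all(vapply(fields, function(f) {
        identical(as.character(occurrences[[f]][i]),
                  as.character(names_tbl[[f]][j]))
      }, logical(1)))
      if (same) {
        pairs[[length(pairs) + 1]] <- c(occ = occurrences$occurrenceID[i],
                                        id = names_tbl$id[j])
      }
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(occ = character(), id = character()))
  }
  as.data.frame(do.call(rbind, pairs), stringsAsFactors = FALSE)
}

# Brute-force subset tally for the issue-overlap partition.
overlap_oracle <- function(flags) {
  classes <- c("misspelling", "format", "conceptual", "synonym")
  out <- integer(15)
  labels <- character(15)
  for (bits in 1:15) {
    members <- as.logical(bitwAnd(bits, c(1L, 2L, 4L, 8L)))
    labels[bits] <- paste(classes[members], collapse = "+")
    for (r in seq_len(nrow(flags))) {
      if (all(flags[r, ] == members)) out[bits] <- out[bits] + 1L
    }
  }
  data.frame(subset = labels, n = out, stringsAsFactors = FALSE)
}

random_string <- function(max_len = 12) {
  paste(sample(letters[1:6], sample(0:max_len, 1), replace = TRUE),
        collapse = "")
}
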