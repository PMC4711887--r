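country	region
United States	North America
United States of America	North America
USA	North America
Canada	North America
Mexico	North America
Guatemala	North America
Belize	North America
Honduras	North America
El Salvador	North America
Nicaragua	North America
Costa Rica	North America
Panama	North America
Cuba	North America
Jamaica	North America
Haiti	North America
Dominican Republic	North America
Bahamas	North America
Greenland	North America
Brazil	South America
Argentina	South America
Chile	South America
Peru	South America
Colombia	South America
Venezuela	South America
Ecuador	South America
Bolivia	South America
Paraguay	South America
Uruguay	South America
Guyana	South America
Suriname	South America
United Kingdom	Europe
France	Europe
Germany	Europe
Spain	Europe
Portugal	Europe
Italy	Europe
Netherlands	Europe
Belgium	Europe
Switzerland	Europe
Austria	Europe
Sweden	Europe
Norway	Europe
Denmark	Europe
Finland	Europe
Iceland	Europe
Ireland	Europe
Poland	Europe
Czech Republic	Europe
Hungary	Europe
Greece	Europe
Russia	Europe
Ukraine	Europe
China	Asia
Japan	Asia
India	Asia
Indonesia	Asia
Malaysia	Asia
Thailand	Asia
Vietnam	Asia
Philippines	Asia
Mongolia	Asia
Kazakhstan	Asia
Iran	Asia
Iraq	Asia
Turkey	Asia
Israel	Asia
Saudi Arabia	Asia
Pakistan	Asia
Afghanistan	Asia
Nepal	Asia
Sri Lanka	Asia
Myanmar	Asia
South Korea	Asia
North Korea	Asia
Laos	Asia
Cambodia	Asia
Egypt	Africa
South Africa	Africa
Kenya	Africa
Tanzania	Africa
Uganda	Africa
Ethiopia	Africa
Nigeria	Africa
Ghana	Africa
Cameroon	Africa
Democratic Republic of the Congo	Africa
Congo	Africa
Madagascar	Africa
Morocco	Africa
Algeria	Africa
Tunisia	Africa
Libya	Africa
Sudan	Africa
Somalia	Africa
Mozambique	Africa
Zimbabwe	Africa
Zambia	Africa
Botswana	Africa
Namibia	Africa
Angola	Africa
Senegal	Africa
Mali	Africa
Gabon	Africa
Australia	Australasia
New Zealand	Australasia
Papua New Guinea	Australasia
Fiji	Oceania
Samoa	Oceania
Tonga	Oceania
Vanuatu	Oceania
Solomon Islands	Oceania
New Caledonia	Oceania
French Polynesia	Oceania
Guam	Oceania
Palau	Oceania
Kiribati	Oceania
Marshall Islands	Oceania
Micronesia	Oceania
Antarctica	Antarctica
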