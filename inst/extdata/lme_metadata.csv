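lme,name,excluded,refHB
1,East Bering Sea,FALSE,TRUE
2,Gulf of Alaska,FALSE,FALSE
3,California Current,FALSE,FALSE
4,Gulf of California,FALSE,FALSE
5,Gulf of Mexico,FALSE,TRUE
6,Southeast U.S. Continental Shelf,FALSE,FALSE
7,Northeast U.S. Continental Shelf,FALSE,FALSE
8,Scotian Shelf,FALSE,FALSE
9,Newfoundland-Labrador Shelf,FALSE,FALSE
10,Insular Pacific-Hawaiian,FALSE,FALSE
11,Pacific Central-American Coastal,FALSE,FALSE
12,Caribbean Sea,FALSE,FALSE
13,Humboldt Current,FALSE,FALSE
14,Patagonian Shelf,FALSE,TRUE
15,South Brazil Shelf,FALSE,FALSE
16,East Brazil Shelf,FALSE,FALSE
17,North Brazil Shelf,FALSE,FALSE
18,Canadian Eastern Arctic-West Greenland,TRUE,FALSE
19,Greenland Sea,FALSE,FALSE
20,Barents Sea,FALSE,TRUE
21,Norwegian Sea,FALSE,FALSE
22,North Sea,FALSE,TRUE
23,Baltic Sea,FALSE,TRUE
24,Celtic-Biscay Shelf,FALSE,FALSE
25,Iberian Coastal,FALSE,FALSE
26,Mediterranean Sea,FALSE,FALSE
27,Canary Current,FALSE,FALSE
28,Guinea Current,FALSE,FALSE
29,Benguela Current,FALSE,TRUE
30,Agulhas Current,FALSE,FALSE
31,Somali Coastal Current,FALSE,FALSE
32,Arabian Sea,FALSE,FALSE
33,Red Sea,FALSE,FALSE
34,Bay of Bengal,FALSE,FALSE
35,Gulf of Thailand,FALSE,FALSE
36,South China Sea,FALSE,FALSE
37,Sulu-Celebes Sea,FALSE,FALSE
38,Indonesian Sea,FALSE,FALSE
39,North Australian Shelf,FALSE,FALSE
40,Northeast Australian Shelf,FALSE,FALSE
41,East-Central Australian Shelf,FALSE,FALSE
42,Southeast Australian Shelf,FALSE,FALSE
43,Southwest Australian Shelf,FALSE,FALSE
44,West-Central Australian Shelf,FALSE,FALSE
45,Northwest Australian Shelf,FALSE,FALSE
46,New Zealand Shelf,FALSE,FALSE
47,East China Sea,FALSE,FALSE
48,Yellow Sea,FALSE,FALSE
49,Kuroshio Current,FALSE,FALSE
50,Sea of Japan,FALSE,FALSE
51,Oyashio Current,FALSE,FALSE
52,Sea of Okhotsk,FALSE,TRUE
53,West Bering Sea,FALSE,FALSE
54,Northern Bering-Chukchi Seas,TRUE,FALSE
55,Beaufort Sea,TRUE,FALSE
56,East Siberian Sea,TRUE,FALSE
57,Laptev Sea,TRUE,FALSE
58,Kara Sea,TRUE,FALSE
59,Iceland Shelf and Sea,FALSE,FALSE
60,Faroe Plateau,FALSE,FALSE
61,Antarctica,TRUE,FALSE
62,Black Sea,TRUE,FALSE
63,Hudson Bay Complex,TRUE,FALSE
64,Central Arctic,TRUE,FALSE
65,Aleutian Islands,FALSE,FALSE
66,Canadian High Arctic-North Greenland,TRUE,FALSE
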