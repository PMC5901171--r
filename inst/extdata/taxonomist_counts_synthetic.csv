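# label: synthetic mammal-like taxonomist counts
# d0: 0
year_start,Y,S,T,D
1755,0,0,1,0
1760,5,0,1,0
1765,10,0,1,0
1770,15,0,1,0
1775,20,0,1,0
1780,25,0,1,0
1785,30,0,1,0
1790,35,0,1,0
1795,40,0,1,0
1800,45,0,1,0
1805,50,0,1,0
1810,55,0,1,0
1815,60,0,1,0
1820,65,0,1,0
1825,70,0,1,0
1830,75,0,1,0
1835,80,0,1,0
1840,85,0,1,0
1845,90,0,1,0
1850,95,0,1,0
1855,100,0,2,0
1860,105,0,2,0
1865,110,0,2,0
1870,115,0,2,0
1875,120,0,2,0
1880,125,0,2,0
1885,130,0,3,0
1890,135,0,3,0
1895,140,0,3,0
1900,145,0,3,0
1905,150,0,4,0
1910,155,0,3,0
1915,160,0,3,0
1920,165,0,5,0
1925,170,0,5,0
1930,175,0,6,0
1935,180,0,4,0
1940,185,0,5,0
1945,190,0,7,0
1950,195,0,8,0
1955,200,0,9,0
1960,205,0,9,0
1965,210,0,10,0
1970,215,0,11,0
1975,220,0,12,0
1980,225,0,13,0
1985,230,0,14,0
1990,235,0,16,0
1995,240,0,17,0
2000,245,0,19,0
2005,250,0,20,0
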