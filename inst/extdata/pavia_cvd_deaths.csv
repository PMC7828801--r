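year,gender,deaths
2010,M,963
2010,F,1424
2011,M,947
2011,F,1353
2012,M,1000
2012,F,1405
2013,M,939
2013,F,1362
2014,M,944
2014,F,1316
2015,M,1054
2015,F,1476
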