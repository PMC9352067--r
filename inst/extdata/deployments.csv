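site_id,subspecies,year,n_deployed,n_complete,n_partial
a,arcticola,2010,51,15,3
a,arcticola,2016,46,16,0
a,arcticola,2017,8,1,0
a,arcticola,2018,40,10,1
b,arcticola,2010,35,4,1
c,arcticola,2010,22,3,2
c,arcticola,2016,13,3,0
d,sakhalina,2013,35,4,6
e,sakhalina,2011,10,4,1
e,sakhalina,2013,15,5,1
e,sakhalina,2016,14,6,1
f,sakhalina,2014,5,3,0
f,sakhalina,2016,7,4,0
g,kistchinski,2017,20,5,0
h,actites,2016,18,1,0
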