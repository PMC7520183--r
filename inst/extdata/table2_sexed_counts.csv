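location,environment,year,month,n_female,n_male
Belle Chain,Rocky reef,2012,June,2,5
Belle Chain,Rocky reef,2012,July,1,9
Belle Chain,Rocky reef,2012,August,18,17
Belle Chain,Rocky reef,2012,September,19,12
Belle Chain,Rocky reef,2013,August,5,5
Belle Chain,Rocky reef,2013,September,14,13
Belle Chain,Rocky reef,2013,October,3,12
Baby Island,Near estuary,2016,April,7,7
Baby Island,Near estuary,2016,May,27,36
Baby Island,Near estuary,2016,June,8,12
Baby Island,Near estuary,2016,July,8,3
Cowichan Bay,Estuary,2012,June,9,7
Cowichan Bay,Estuary,2012,July,16,20
Cowichan Bay,Estuary,2012,August,7,13
Cowichan Bay,Estuary,2012,September,19,7
Cowichan Bay,Estuary,2012,October,13,16
Cowichan Bay,Estuary,2012,November,2,4
Cowichan Bay,Estuary,2013,April,10,1
Cowichan Bay,Estuary,2013,May,11,4
Cowichan Bay,Estuary,2013,June,9,3
Cowichan Bay,Estuary,2013,July,8,7
Cowichan Bay,Estuary,2013,August,15,4
Cowichan Bay,Estuary,2013,September,12,10
Cowichan Bay,Estuary,2013,October,12,9
Cowichan Bay,Estuary,2013,November,7,8
Cowichan Bay,Estuary,2014,May,6,10
Cowichan Bay,Estuary,2014,June,6,8
Cowichan Bay,Estuary,2014,July,0,1
Cowichan Bay,Estuary,2014,August,2,3
Cowichan Bay,Estuary,2014,September,8,9
Cowichan Bay,Estuary,2014,October,24,37
Cowichan Bay,Estuary,2014,November,1,23
Comox,Near estuary,2012,May,4,15
Comox,Near estuary,2012,June,11,18
Comox,Near estuary,2012,July,13,22
Comox,Near estuary,2012,August,9,11
Comox,Near estuary,2012,September,20,10
Comox,Near estuary,2012,October,16,8
Comox,Near estuary,2013,April,4,13
Comox,Near estuary,2013,May,12,5
Comox,Near estuary,2013,June,5,8
Comox,Near estuary,2013,July,7,11
Comox,Near estuary,2013,August,10,10
Comox,Near estuary,2013,September,16,9
Comox,Near estuary,2013,October,11,7
Fraser River,Estuary,2012,May,0,13
Fraser River,Estuary,2012,June,3,17
Fraser River,Estuary,2012,July,2,21
Fraser River,Estuary,2012,August,2,6
Fraser River,Estuary,2012,September,13,29
Fraser River,Estuary,2012,October,5,13
Fraser River,Estuary,2013,April,5,9
Fraser River,Estuary,2013,May,4,15
Fraser River,Estuary,2013,June,1,3
Fraser River,Estuary,2013,July,1,5
Fraser River,Estuary,2013,August,3,2
Fraser River,Estuary,2013,September,7,20
Fraser River,Estuary,2013,October,5,12
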