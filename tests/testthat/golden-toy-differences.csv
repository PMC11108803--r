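scenario,year,sex,measure,avoided,avoided_per_100k,cumulative_person_years
constant,2014,all,deaths,-38.071835338923847,-13.265919065394652,286989.8056157878
constant,2014,all,dementia_cases,-4.7055888250297357,-1.6396362285179626,286989.8056157878
constant,2014,all,disability_cases,-19.214487702204678,-6.6951812664483219,286989.8056157878
constant,2014,men,deaths,-19.878193649786226,-13.852891817626775,143494.9028078939
constant,2014,men,dementia_cases,-2.4677122167167909,-1.719721166695712,143494.9028078939
constant,2014,men,disability_cases,-10.07649155159379,-7.022194764007649,143494.9028078939
constant,2014,women,deaths,-18.193641689137621,-12.67894631316253,143494.9028078939
constant,2014,women,dementia_cases,-2.2378766083128312,-1.5595512903401345,143494.9028078939
constant,2014,women,disability_cases,-9.1379961506108884,-6.3681677688889948,143494.9028078939
constant,2015,all,deaths,-108.38376188068287,-19.157903537311643,565739.15652929503
constant,2015,all,dementia_cases,-14.95603735699342,-2.6436277539539494,565739.15652929503
constant,2015,all,disability_cases,-54.161962392192436,-9.5736633689041515,565739.15652929503
constant,2015,men,deaths,-56.601491243603959,-20.00974851761848,282869.57826464751
constant,2015,men,dementia_cases,-7.8453459380666573,-2.7734852175325471,282869.57826464751
constant,2015,men,disability_cases,-28.407409455408924,-10.042582037164662,282869.57826464751
constant,2015,women,deaths,-51.782270637078909,-18.306058557004803,282869.57826464751
constant,2015,women,dementia_cases,-7.1106914189265353,-2.5137702903752714,282869.57826464751
constant,2015,women,disability_cases,-25.754552936783057,-9.1047447006434794,282869.57826464751
constant,2016,all,deaths,-205.77448551987709,-24.596559756927615,836598.6444991387
constant,2016,all,dementia_cases,-31.192877607340279,-3.728535518488088,836598.6444991387
constant,2016,all,disability_cases,-101.84348274712193,-12.173517542344856,836598.6444991387
constant,2016,men,deaths,-107.4835397206316,-25.695365496314107,418299.32224956935
constant,2016,men,dementia_cases,-16.3664351930679,-3.9126133662017306,418299.32224956935
constant,2016,men,disability_cases,-53.422431937517558,-12.771340783010929,418299.32224956935
constant,2016,women,deaths,-98.290945799245037,-23.49775401754102,418299.32224956935
constant,2016,women,dementia_cases,-14.826442414272151,-3.5444576707743911,418299.32224956935
constant,2016,women,disability_cases,-48.421050809603912,-11.575694301678674,418299.32224956935
constant,2017,all,deaths,-325.68448750665266,-29.610349292292995,1099900.8633492279
constant,2017,all,dementia_cases,-53.554873364062814,-4.8690636718828255,1099900.8633492279
constant,2017,all,disability_cases,-159.67444408165284,-14.517166901336893,1099900.8633492279
constant,2017,men,deaths,-170.14947996122191,-30.939057442524803,549950.43167461397
constant,2017,men,dementia_cases,-28.105485874792407,-5.1105489251477518,549950.43167461397
constant,2017,men,disability_cases,-83.767519310882108,-15.231830813516728,549950.43167461397
constant,2017,women,deaths,-155.53500754543029,-28.281641142061108,549950.43167461397
constant,2017,women,dementia_cases,-25.44938748927018,-4.6275784186178575,549950.43167461397
constant,2017,women,disability_cases,-75.906924770770274,-13.802502989156974,549950.43167461397
optimistic,2014,all,deaths,86.129394978352138,30.011308169482241,286989.8056157878
optimistic,2014,all,dementia_cases,10.645389561830598,3.7093267264281451,286989.8056157878
optimistic,2014,all,disability_cases,43.468674044142062,15.146417466248415,286989.8056157878
optimistic,2014,men,deaths,44.970166977166627,31.339208638909746,143494.9028078939
optimistic,2014,men,dementia_cases,5.5826717654774711,3.8905017922144332,143494.9028078939
optimistic,2014,men,disability_cases,22.795909709032912,15.886215651542203,143494.9028078939
optimistic,2014,women,deaths,41.159228001185511,28.683407700054744,143494.9028078939
optimistic,2014,women,dementia_cases,5.0627177963532404,3.5281516606419356,143494.9028078939
optimistic,2014,women,disability_cases,20.67276433510915,14.406619280954629,143494.9028078939
optimistic,2015,all,deaths,232.08502831516489,41.023327736224509,565739.15652929503
optimistic,2015,all,dementia_cases,32.027249726923401,5.6611336438871671,565739.15652929503
optimistic,2015,all,disability_cases,115.9114982038227,20.488505500470975,565739.15652929503
optimistic,2015,men,deaths,121.20297768476757,42.847653829841093,282869.57826464751
optimistic,2015,men,dementia_cases,16.799510973028532,5.938959953237255,282869.57826464751
optimistic,2015,men,disability_cases,60.795828587532014,21.492529865001096,282869.57826464751
optimistic,2015,women,deaths,110.88205063039732,39.199001642607932,282869.57826464751
optimistic,2015,women,dementia_cases,15.227738753894869,5.3833073345370774,282869.57826464751
optimistic,2015,women,disability_cases,55.115669616290234,19.484481135940694,282869.57826464751
optimistic,2016,all,deaths,417.65800432912783,49.923342223339908,836598.6444991387
optimistic,2016,all,dementia_cases,63.303652586172575,7.5667888063662465,836598.6444991387
optimistic,2016,all,disability_cases,206.4183482149183,24.673521714644711,836598.6444991387
optimistic,2016,men,deaths,218.16150590666848,52.154401000082686,418299.32224956935
optimistic,2016,men,dementia_cases,33.211339040690405,7.9396110091891492,418299.32224956935
optimistic,2016,men,disability_cases,108.28421985798104,25.886778700869034,418299.32224956935
optimistic,2016,women,deaths,199.49649842245935,47.692283446597131,418299.32224956935
optimistic,2016,women,dementia_cases,30.092313545482284,7.1939666035433714,418299.32224956935
optimistic,2016,women,disability_cases,98.134128356936799,23.460264728420277,418299.32224956935
optimistic,2017,all,deaths,627.42842308914987,57.044088608005396,1099900.8633492279
optimistic,2017,all,dementia_cases,103.12842292521032,9.3761561938574598,1099900.8633492279
optimistic,2017,all,disability_cases,306.83269284180278,27.896395308527072,1099900.8633492279
optimistic,2017,men,deaths,327.80108604232919,59.605569368163962,549950.43167461397
optimistic,2017,men,dementia_cases,54.113673621374915,9.8397365480007561,549950.43167461397
optimistic,2017,men,disability_cases,160.98683664850432,29.272972140106344,549950.43167461397
optimistic,2017,women,deaths,299.62733704682068,54.482607847846815,549950.43167461397
optimistic,2017,women,dementia_cases,49.014749303835515,8.9125758397141865,549950.43167461397
optimistic,2017,women,disability_cases,145.845856193298,26.519818476947719,549950.43167461397
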