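scenario,year,sex,le,hle
baseline,2015,all,34.062812894704599,29.132026451315731
baseline,2015,men,34.062812894704599,29.132026451315731
baseline,2015,women,34.062812894704599,29.132026451315731
baseline,2017,all,34.986962200997837,28.533915600999446
baseline,2017,men,34.986962200997837,28.533915600999446
baseline,2017,women,34.986962200997837,28.533915600999446
constant,2015,all,33.768119761324876,28.87461433347088
constant,2015,men,33.755098600753314,28.863214081128898
constant,2015,women,33.781150696302504,28.886023153524778
constant,2017,all,34.411681784318439,28.032623831990655
constant,2017,men,34.38610520344686,28.01021555083933
constant,2017,women,34.437294300064458,28.055063741666157
optimistic,2015,all,34.691673406211969,29.68276731206182
optimistic,2015,men,34.720244088820976,29.707850660711131
optimistic,2015,women,34.663148402923134,29.657724116062568
optimistic,2017,all,36.045968581437748,29.467990754440024
optimistic,2017,men,36.095358833698285,29.511818765983893
optimistic,2017,women,35.9967052576852,29.424275938884186
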