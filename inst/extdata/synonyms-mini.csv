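word,pos,synonym
sad,a,unhappy
sad,a,sorrowful
sad,a,deplorable
sad,a,lamentable
unhappy,a,sad
unhappy,a,dysphoric
unhappy,a,infelicitous
depressed,a,dejected
depressed,a,gloomy
depressed,a,downcast
depressed,v,deject
shallow,a,superficial
shallow,a,fiddling
shallow,a,trivial
pathetic,a,pitiable
pathetic,a,ridiculous
pathetic,a,wretched
pathetic,a,silly
immoral,a,base
immoral,a,wrong
immoral,a,unethical
understandable,a,comprehensible
understandable,a,apprehensible
understandable,a,easily_understood
brave,a,courageous
brave,a,fearless
brave,a,valiant
brave,a,gallant
brave,v,weather
brave,v,endure
motivated,a,driven
motivated,v,actuate
motivated,v,impel
motivated,v,incite
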