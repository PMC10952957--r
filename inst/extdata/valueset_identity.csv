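"dimension","level","decrement"
"MO",1,0
"MO",2,0
"MO",3,0
"MO",4,0
"MO",5,0
"SC",1,0
"SC",2,0
"SC",3,0
"SC",4,0
"SC",5,0
"UA",1,0
"UA",2,0
"UA",3,0
"UA",4,0
"UA",5,0
"PD",1,0
"PD",2,0
"PD",3,0
"PD",4,0
"PD",5,0
"AD",1,0
"AD",2,0
"AD",3,0
"AD",4,0
"AD",5,0
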