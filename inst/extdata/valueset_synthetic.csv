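"dimension","level","decrement"
"MO",1,0
"MO",2,0.04
"MO",3,0.07
"MO",4,0.16
"MO",5,0.27
"SC",1,0
"SC",2,0.03
"SC",3,0.06
"SC",4,0.14
"SC",5,0.21
"UA",1,0
"UA",2,0.03
"UA",3,0.06
"UA",4,0.12
"UA",5,0.19
"PD",1,0
"PD",2,0.05
"PD",3,0.09
"PD",4,0.23
"PD",5,0.33
"AD",1,0
"AD",2,0.05
"AD",3,0.08
"AD",4,0.2
"AD",5,0.29
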