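id,sex,age,bmi,scoff_sick,scoff_control,scoff_one_stone,scoff_fat,scoff_food
W1,female,24,16.5,0,0,1,1,0
W2,female,31,21,1,1,0,0,0
W3,female,45,34,0,1,0,0,1
N1,female,28,22,0,0,1,0,0
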