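"file","md5"
"table1a_male.csv","2fe4273c5cba351eaef13b012ffeb5bd"
"table1b_female.csv","23ca1df651d9677463d96634611f79fe"
"table1c_pooled.csv","1763aac9799dbfdac2426373449507bd"
"table2_drivers.csv","b4bd746bc51550392a7ed49dab41173c"
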