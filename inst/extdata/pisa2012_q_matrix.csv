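item,uncertainty,average,statistical_chart,data_handling
PM942Q01,1,1,0,0
PM942Q02,0,1,0,1
PM942Q03,0,1,0,0
PM957Q01,0,1,0,1
PM957Q02,0,1,0,0
PM957Q03,0,1,0,1
PM985Q01,1,0,1,1
PM985Q02,0,0,1,1
PM985Q03,0,0,1,0
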