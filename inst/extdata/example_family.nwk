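((((t9:0.3003101915,(t6:0.5929288475,(t8:0.2380232813,t4:0.8231869878):0.5329497182):0.07264320855):0.2918686506,t1:0.3492440532):0.1541864066,(t3:0.1016243151,t10:0.8320755605):0.2367582193):0.09259337652,((t2:0.3739625944,t7:0.1563042833):0.9389337793,t5:0.1237213484):0.4038794683);
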