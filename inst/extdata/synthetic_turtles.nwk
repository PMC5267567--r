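(((((sp_028:0.5971691546,(sp_001:0.4687973196,(sp_038:0.3366272099,sp_040:0.3366272099):0.1321701097):0.128371835):0.9554758566,((((sp_017:0.4155875683,sp_027:0.4155875683):0.2851394182,sp_036:0.7007269865):0.02674736786,((sp_003:0.1895154871,sp_011:0.1895154871):0.2764815181,sp_005:0.4659970052):0.2614773491):0.3044813559,sp_018:1.03195571):0.5206893009):0.4449007578,((((((sp_029:0.7399361485,sp_020:0.7399361485):0.4763617323,sp_022:1.216297881):0.006169036571,(sp_031:0.06153747811,sp_004:0.06153747811):1.160929439):0.1989162689,sp_033:1.421383186):0.2853287984,(sp_006:0.693538566,(sp_015:0.2203246892,sp_024:0.2203246892):0.4732138767):1.013173419):0.1934952527,(((sp_016:0.08176773388,sp_010:0.08176773388):1.643637561,((sp_032:0.4120898451,sp_014:0.4120898451):0.9260768567,sp_039:1.338166702):0.3872385936):0.1599132524,((sp_002:0.004834062821,sp_034:0.004834062821):0.3051646154,(sp_008:0.2358844047,sp_023:0.2358844047):0.0741142736):1.575319869):0.01488868962):0.09733853166):0.932885662,((sp_013:0.6652590983,(sp_026:0.102302174,sp_012:0.102302174):0.5629569242):1.815064326,(sp_030:1.023282065,sp_007:1.023282065):1.457041359):0.4501080069):0.7397976005,(((sp_009:0.3070931718,sp_019:0.3070931718):0.4824928298,sp_037:0.7895860017):0.2357900904,((sp_025:0.1010682577,sp_021:0.1010682577):0.05477982265,sp_035:0.1558480803):0.8695280117):2.644852939);
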