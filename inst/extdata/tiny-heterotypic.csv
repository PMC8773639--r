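condition,ratio,time_h,channel,count,replicate
heterotypic,1,0,red,2677.38,1
heterotypic,1,12,red,3470.241,1
heterotypic,1,24,red,5149.646,1
heterotypic,1,36,red,7155.773,1
heterotypic,1,48,red,9368.563,1
heterotypic,1,60,red,11854.176,1
heterotypic,1,72,red,16597.133,1
heterotypic,1,84,red,19809.641,1
heterotypic,1,96,red,28511.483,1
heterotypic,1,108,red,33263.589,1
heterotypic,1,120,red,46106.034,1
heterotypic,1,132,red,62690.517,1
heterotypic,1,144,red,67530.86,1
heterotypic,1,0,green,2465.393,1
heterotypic,1,12,green,3525.162,1
heterotypic,1,24,green,5185.485,1
heterotypic,1,36,green,6788.887,1
heterotypic,1,48,green,7984.85,1
heterotypic,1,60,green,10477.04,1
heterotypic,1,72,green,16328.022,1
heterotypic,1,84,green,19468.406,1
heterotypic,1,96,green,23418.904,1
heterotypic,1,108,green,32859.025,1
heterotypic,1,120,green,45588.583,1
heterotypic,1,132,green,61060.234,1
heterotypic,1,144,green,70367.216,1
heterotypic,4,0,red,3948.876,1
heterotypic,4,12,red,5222.824,1
heterotypic,4,24,red,8163.481,1
heterotypic,4,36,red,10459.093,1
heterotypic,4,48,red,14548.497,1
heterotypic,4,60,red,19109.966,1
heterotypic,4,72,red,25105.123,1
heterotypic,4,84,red,29913.341,1
heterotypic,4,96,red,40951.065,1
heterotypic,4,108,red,47441.349,1
heterotypic,4,120,red,64343.406,1
heterotypic,4,132,red,83020.177,1
heterotypic,4,144,red,99391.908,1
heterotypic,4,0,green,1001.808,1
heterotypic,4,12,green,1432.443,1
heterotypic,4,24,green,1946.048,1
heterotypic,4,36,green,2785.763,1
heterotypic,4,48,green,3405.947,1
heterotypic,4,60,green,4278.908,1
heterotypic,4,72,green,6050.261,1
heterotypic,4,84,green,7354.593,1
heterotypic,4,96,green,10659.792,1
heterotypic,4,108,green,12565.012,1
heterotypic,4,120,green,17173.777,1
heterotypic,4,132,green,21864.605,1
heterotypic,4,144,green,26782.078,1
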