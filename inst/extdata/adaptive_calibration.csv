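"diameter_mm","v_cc","lb_nominal","lb_meas","eps","pct_error"
12,0.90477868423386,3,1.94110347062158,0.686201865838475,16.551236570793
12,0.90477868423386,5,2.88220694124317,0.686201865838475,16.551236570793
12,0.90477868423386,8,4.29386214717554,0.686201865838475,16.551236570793
12,0.90477868423386,12,6.17606908841871,0.686201865838475,16.551236570793
12,0.90477868423386,20,9.94048297090505,0.686201865838475,16.551236570793
12,0.90477868423386,30,14.646000324013,0.686201865838475,16.551236570793
16,2.14466058485063,3,2.14223255539052,0.63466179497939,3.47030641631553
16,2.14466058485063,5,3.28446511078103,0.63466179497939,3.47030641631553
16,2.14466058485063,8,4.9978139438668,0.63466179497939,3.47030641631553
16,2.14466058485063,12,7.28227905464784,0.63466179497939,3.47030641631553
16,2.14466058485063,20,11.8512092762099,0.63466179497939,3.47030641631553
16,2.14466058485063,30,17.5623720531625,0.63466179497939,3.47030641631553
20,4.18879020478639,3,2.27562850272631,0.52561932230747,0.57214432189715
20,4.18879020478639,5,3.55125700545262,0.52561932230747,0.57214432189715
20,4.18879020478639,8,5.46469975954208,0.52561932230747,0.57214432189715
20,4.18879020478639,12,8.0159567649947,0.52561932230747,0.57214432189715
20,4.18879020478639,20,13.1184707758999,0.52561932230747,0.57214432189715
20,4.18879020478639,30,19.4966132895315,0.52561932230747,0.57214432189715
24,7.23822947387088,3,2.35241609211094,0.568342507933959,-3.30149343857478
24,7.23822947387088,5,3.70483218422188,0.568342507933959,-3.30149343857478
24,7.23822947387088,8,5.73345632238828,0.568342507933959,-3.30149343857478
24,7.23822947387088,12,8.43828850661016,0.568342507933959,-3.30149343857478
24,7.23822947387088,20,13.8479528750539,0.568342507933959,-3.30149343857478
24,7.23822947387088,30,20.6100333356086,0.568342507933959,-3.30149343857478
28,11.4940403219339,3,2.44817215276366,0.533484689447117,-0.304295529494921
28,11.4940403219339,5,3.89634430552731,0.533484689447117,-0.304295529494921
28,11.4940403219339,8,6.06860253467279,0.533484689447117,-0.304295529494921
28,11.4940403219339,12,8.9649468402001,0.533484689447117,-0.304295529494921
28,11.4940403219339,20,14.7576354512547,0.533484689447117,-0.304295529494921
28,11.4940403219339,30,21.998496215073,0.533484689447117,-0.304295529494921
36,24.4290244743142,3,2.58717928979918,0.558182057593513,2.27475682376947
36,24.4290244743142,5,4.17435857959836,0.558182057593513,2.27475682376947
36,24.4290244743142,8,6.55512751429713,0.558182057593513,2.27475682376947
36,24.4290244743142,12,9.72948609389548,0.558182057593513,2.27475682376947
36,24.4290244743142,20,16.0782032530922,0.558182057593513,2.27475682376947
36,24.4290244743142,30,24.0140997020881,0.558182057593513,2.27475682376947
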