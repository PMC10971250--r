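pair,psnr_db,ssim
1,26.280722159514,0.985546400531
2,26.441608359723,0.986269251636
3,26.429825995101,0.986104971443
4,26.157663374856,0.985280063697
5,26.159041379025,0.985126855196
6,26.369407013199,0.985730198120
7,26.206328600938,0.985025740957
8,26.149889486878,0.984960847497
9,26.272639539829,0.984564750536
10,26.332884394648,0.985940446217
11,26.055715563229,0.984409027785
12,26.331011153545,0.984997521017
13,26.284435844960,0.985002705349
14,26.487114074242,0.986050766664
15,26.241842726470,0.985297306703
16,26.197133663735,0.984693410822
17,26.331024253711,0.985418636590
18,26.237685018985,0.985566806227
19,26.216217387687,0.985384924147
20,26.040824004196,0.984614191492
21,26.162909789802,0.984752069122
22,26.196628459103,0.984877657541
23,26.324142595172,0.986110807577
24,26.392414274016,0.986035355236
25,26.488781381976,0.985619151343
26,26.367182833443,0.986093268022
27,26.196285581207,0.985353940760
28,26.256776218585,0.985104602468
29,26.097597497882,0.985089879197
30,26.319768102447,0.984962890444
31,26.252189850779,0.984908511497
32,26.255205269217,0.985868764001
33,26.304374860078,0.985288892147
34,26.316163633890,0.985938535018
35,26.135741985582,0.984902153849
36,26.190856938619,0.985026881476
37,26.360931318337,0.985550100003
38,26.168369660739,0.985052694628
39,26.194719975781,0.985076475420
40,26.163603690580,0.985514382335
41,26.317368294887,0.985524721227
42,26.291397042640,0.985127230709
43,26.265427333486,0.985534810691
44,26.329788304712,0.985908802954
45,26.295039133356,0.985559837441
46,26.210436155184,0.985087428243
47,26.354938838973,0.985846553195
48,26.356513379661,0.985569570860
49,26.106027629075,0.984566802436
50,26.356947483409,0.985380069447
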