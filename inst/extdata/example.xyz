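5
frame 1
CA -5.2318 4.4585 9.5207
CA -0.8170 2.5774 8.9011
CA 0.5994 2.7807 7.1841
CA 1.0527 5.5125 5.9941
CA -4.5135 10.0624 8.1616
5
frame 2
CA 6.1401 0.1410 3.9532
CA 8.6183 2.5710 5.9382
CA 9.9124 3.7393 4.7933
CA 9.3800 5.3484 3.1342
CA 3.3440 2.6891 -0.4439
5
frame 3
CA 6.0133 -0.4335 -0.3862
CA 2.3593 -3.3330 -1.3074
CA 2.2663 -5.2019 -0.8798
CA 2.5926 -6.1377 1.4606
CA 7.8115 -1.5973 4.5198
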