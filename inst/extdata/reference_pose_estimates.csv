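instance,method,wx,wy,wz,theta_deg,a_deg,s,tx,ty,tz
1,ground_truth,1.1644,1.7179,2.3026,177.605,NA,0.5,4,5,-2
1,horn,1.1585,1.7389,2.2862,177.453,0.501631,0.4979,4.0061,4.9494,-2.0102
1,filtered_d4,1.1575,1.7313,2.2979,177.688,0.29074,0.4985,4.0647,5.0015,-1.9969
1,filtered_d2,1.1571,1.7264,2.3034,177.751,0.200769,0.4985,4.0011,4.9975,-1.9811
2,ground_truth,-2.1374,-1.4560,1.0740,160.446,NA,1.5,-3,-2,-2
2,horn,-2.1505,-1.4359,1.0556,160.029,0.60166,1.5077,-3.1509,-2.0992,-1.9921
2,filtered_d4,-2.1475,-1.4559,1.0578,160.533,0.38816,1.4971,-3.0295,-1.9922,-1.9528
2,filtered_d2,-2.1531,-1.4479,1.0615,160.621,0.43790,1.4971,-3.0436,-2.0111,-1.9419
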