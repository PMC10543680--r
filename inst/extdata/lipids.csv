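name,area,volume,D1,D2,D3,rhoX1,rhoX2,rhoX3,rhoN1,rhoN2,rhoN3,sigma1,sigma2,sigma3
DPPC,57,1140,12.0,10.7,3.50,0.412,0.317,0.245,4.203,-0.349,-0.602,2.49,2.39,2.01
DOPC,60,1270,11.9,9.9,5.87,0.408,0.302,0.264,4.294,-0.265,-0.446,3.50,3.48,4.02
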