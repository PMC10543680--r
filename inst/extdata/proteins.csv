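name,pdb,Mw,Vp,R,delta,phiI,phiE,L,rhoPX,rhoPN
aquaporin,3d9s,102505,133006,5.78,28.6,0.211,0.904,41.4,0.411,2.828
bacteriorhodopsin,1fbb,73690,96506,8.01,21.0,0.0195,0.870,45.5,0.411,2.732
ATPase,3wgv,109942,138965,18.2,24.6,1.00,0.0557,107,0.420,3.009
cytochrome_c,1giw,11721,14839,0.262,15.0,0.718,0.886,22.8,0.420,3.119
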