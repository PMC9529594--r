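%OpenBCI Raw EEG Data
%Number of channels = 16
%Sample Rate = 250 Hz
0,13.710,-5.647,3.631,6.329,4.043,-1.061,15.115,-0.947,20.184,-0.627,13.049,22.866,-13.889,-2.788,-1.333,6.360
1,-2.843,-26.565,-24.405,13.201,-3.066,-17.813,-1.719,12.147,18.952,-4.305,-2.573,-17.632,4.601,-6.400,4.555,7.048
2,10.351,-6.089,5.050,-17.170,-7.845,-8.509,-24.142,0.361,2.060,-3.611,7.582,-7.267,-13.683,4.328,-8.114,14.441
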