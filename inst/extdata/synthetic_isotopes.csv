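sample,d13C,d15N,collagen_yield,cn_ratio
SY001,-9.5,9.8,4.3,3.06
SY002,-11.9,10.8,3.4,3.24
SY003,-13.2,9.8,9.5,3.09
SY004,-10.6,11.8,4.1,3.04
SY005,-11.7,7.3,9.4,3.15
SY006,-9,9.5,6.3,3.11
SY007,-12.2,10.2,7.1,3.37
SY008,-10,10.6,10.7,3.36
SY009,-11.8,11.3,3.2,3.13
SY010,-8,8.9,9.9,3.18
SY011,-8.3,12.5,3.8,3.27
SY012,-11.2,10.2,11.6,3.28
SY013,-10.6,9.9,7.3,3.43
SY014,-11.6,8.5,9.2,3.06
SY015,-8.4,9.8,5.8,3.28
SY016,-9.8,9.5,3.4,3.37
SY017,-10.9,9.7,6.5,3.14
SY018,-9.4,9.3,6.4,3.11
SY019,-12.6,11.4,5.6,3.4
SY020,-11.5,11.1,9.7,3.31
SY021,-10.5,9.3,2.9,3.42
SY022,-9.7,7.1,3.6,3.46
SY023,-9.9,6.9,4,3.39
SY024,-9.7,12.5,7.4,3
SY025,-8.7,11.2,8.6,3.18
SY026,-11.7,9,5.7,3.05
SY027,-9.3,10.5,6.6,3.42
SY028,-6.7,7.9,7.6,3.12
SY029,-12.3,9.1,3.7,3.37
SY030,-9.3,8.7,4.1,3.49
SY031,-11.1,4.9,11,3.39
SY032,-11,11.4,6.2,3.39
SY033,-8.4,11.7,2,3.05
SY034,-10.7,11.8,5.3,3.14
SY035,-9.8,11.2,6.3,3.17
SY036,-10.7,10,4.7,3.33
SY037,-10.3,10.2,2.1,3.47
SY038,-13.3,7.6,7.2,3.41
SY039,-9.3,9.4,11.8,3.14
SY040,-8.1,9.4,8.5,3.04
SY041,-8.9,12.6,7.5,3.14
SY042,-9.8,9.9,9.1,3.37
SY043,-8.9,7.9,3.4,3.07
SY044,-11.7,10.2,2.9,3.12
SY045,-8.4,11.7,9.1,3.16
SY046,-10.9,8.5,2.4,3.2
SY047,-10.5,9.8,9.4,3.16
SY048,-10.6,9.2,4.8,3.03
SY049,-10,9.5,8.7,3.22
SY050,-10,9.4,10.6,3.4
SY051,-11.9,10.7,4.3,3.33
SY052,-10.2,10.8,6.7,3.03
SY053,-9.7,8.9,11.8,3.13
SY054,-10.9,8.2,6,3.34
SY055,-9.8,10.9,0.4,3.2
SY056,-10.4,9,0.9,3.1
SY057,-10.3,8.7,5,3.8
SY058,-10.7,10.8,6,2.7
SY059,-7.6,11.5,NA,3.2
SY060,-8.2,11.9,7,NA
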