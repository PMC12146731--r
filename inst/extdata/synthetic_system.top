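; synthetic topology fixture
[ defaults ]
  1  2  yes  1.0  1.0

[ atomtypes ]
;name  at.num  mass      charge  ptype  sigma        epsilon
CAL    20      40.08000  0.00    A      0.24357170954  0.50208
SOD    11      22.98977  0.00    A      0.25160        0.19624
OT     8       15.99940  0.00    A      0.31507        0.63639

[ nonbond_params ]
; i    j   func  sigma    epsilon
CAL    OC  1     0.30     0.40
CAL    OT  1     0.31     0.42
SOD    OC  1     0.29     0.35
POT    OC  1     0.32     0.30

[ moleculetype ]
PROT  3

[ atoms ]
;nr type resnr residu atom cgnr charge  mass
  1  CT2   1   GLU    CB    1  -0.18  12.011
  2  HA2   1   GLU    HB1   1   0.09   1.008
  3  HA2   1   GLU    HB2   1   0.09   1.008
  4  CT2   1   GLU    CG    2  -0.28  12.011
  5  HA2   1   GLU    HG1   2   0.09   1.008
  6  HA2   1   GLU    HG2   2   0.09   1.008
  7  CC    1   GLU    CD    2   0.62  12.011
  8  OC    1   GLU    OE1   2  -0.76  15.999
  9  OC    1   GLU    OE2   2  -0.76  15.999
 10  CAL   2   CA     CA    3   2.00  40.080
 11  SOD   3   NA     NA    4   1.00  22.990
 12  OT    4   SOL    OW    5  -0.834 15.999
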