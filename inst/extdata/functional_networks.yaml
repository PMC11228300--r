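salience:
- AI
- BLA
- CEA
- MEA
- MED
- DR
- CLA
social:
- HPF
- ACA
- PL
- VTA
- MD
- ACB
- MPO
- MEA
- CEA
- BLA
default_mode:
- STRd
- VISp
- BMA
- LAT
- ZI
- CS
- ACA
- PL
- HPF
- MEA
lateral_cortical:
- MOp
- SSp
- VPM
- ACA
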