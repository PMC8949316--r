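# Default lipid composition profiles for the synthetic-section generator.
#
# Class shares are shares of total ion current per ion mode (sum to 1 per
# polarity); species_molpct lists the within-class mole percentages reported
# for MALDI-IMS of the MKI67+ proliferative cluster in human healthy and
# glioblastoma (GBM) brain tissue, with and without ex vivo temozolomide
# (TMZ) treatment. Unlisted panel species share the class remainder equally.
#
# The class shares encode, after TIC normalization, the reported fold
# changes: GBM vs healthy PE x1.5, PI x3.6, SM x1.8, sulfatide /2.9;
# TMZ-treated vs vehicle healthy PI x2.2, HexCer /1.8, sulfatide /1.6.
# PS/PG (negative mode) and PC/Cer/DG (positive mode) absorb the
# compensating share, mirroring classes with no reported change.
#
# bulk_parenchyma is the surrounding non-proliferative tissue composition
# (white-matter-like, sulfatide/HexCer-rich, long-chain species dominant);
# it is a synthetic design choice, not a measured profile.
arms:
  healthy_vehicle:
    class_shares:
      negative: {PE: 0.22, PE_P: 0.20, PI: 0.06, PS: 0.14, PG: 0.05, Sulf: 0.33}
      positive: {PC: 0.50, SM: 0.20, HexCer: 0.15, Cer: 0.08, DG: 0.07}
    species_molpct:
      PE:   {"36:1": 35.6, "40:6": 13.9, "38:4": 11.3, "34:0": 3.2, "38:1": 6.1}
      PE_P: {"36:2": 20.8, "38:4": 14.7, "34:1": 13.7, "40:6": 10.2,
             "36:4": 1.9, "38:6": 2.8, "40:5": 7.1, "40:7": 1.8}
      PI:   {"38:4": 54.9, "38:5": 5.1}
      SM:   {"d36:1": 41.0, "d42:2": 26.8, "d34:1": 10.6}
      Sulf: {"d42:2": 50.8, "t42:1": 15.9, "d42:1": 11.3}
      PS:   {"36:1": 30.0, "40:6": 25.0, "38:4": 15.0}
      PG:   {"34:1": 35.0, "36:2": 20.0}
      PC:   {"34:1": 32.0, "32:0": 18.0, "36:1": 15.0, "34:0": 10.0}
      Cer:  {"d42:1": 28.0, "d34:1": 22.0, "d36:1": 18.0}
      HexCer: {"d42:2": 30.0, "d42:1": 22.0, "d44:2": 12.0}
      DG:   {"34:1": 30.0, "36:2": 22.0, "38:4": 15.0}
  gbm_vehicle:
    class_shares:
      negative: {PE: 0.33, PE_P: 0.20, PI: 0.216, PS: 0.103310,
                 PG: 0.036897, Sulf: 0.113793}
      positive: {PC: 0.40, SM: 0.36, HexCer: 0.12, Cer: 0.064, DG: 0.056}
    species_molpct:
      PE:   {"36:1": 30.0, "38:4": 13.4, "36:2": 10.1}
      PE_P: {"38:4": 22.0, "36:4": 14.8, "40:6": 10.4, "38:6": 10.3,
             "36:2": 3.6, "40:5": 4.3}
      PI:   {"38:4": 75.7}
      SM:   {"d34:1": 37.5, "d36:1": 26.6, "d36:2": 8.3}
      Sulf: {"d42:2": 23.9, "d36:3": 21.0, "d36:4": 11.4}
      PS:   {"36:1": 30.0, "40:6": 25.0, "38:4": 15.0}
      PG:   {"34:1": 35.0, "36:2": 20.0}
      PC:   {"34:1": 32.0, "32:0": 18.0, "36:1": 15.0, "34:0": 10.0}
      Cer:  {"d42:1": 28.0, "d34:1": 22.0, "d36:1": 18.0}
      HexCer: {"d42:2": 30.0, "d42:1": 22.0, "d44:2": 12.0}
      DG:   {"34:1": 30.0, "36:2": 22.0, "38:4": 15.0}
  healthy_tmz:
    class_shares:
      negative: {PE: 0.22, PE_P: 0.20, PI: 0.132, PS: 0.178132,
                 PG: 0.063618, Sulf: 0.206250}
      positive: {PC: 0.539216, SM: 0.215686, HexCer: 0.083333,
                 Cer: 0.086275, DG: 0.075490}
    species_molpct:
      PE:   {"36:1": 27.1, "40:6": 23.2, "38:4": 15.8, "34:0": 5.5, "38:1": 4.0}
      PE_P: {"40:6": 23.5, "38:4": 20.4, "40:4": 11.5, "38:6": 6.5,
             "40:7": 3.2, "34:1": 5.0, "36:2": 7.3}
      PI:   {"38:4": 80.4, "38:5": 6.3}
      SM:   {"d36:1": 50.1, "d38:1": 12.4, "d42:2": 12.1}
      Sulf: {"d42:2": 50.8, "t42:1": 15.9, "d42:1": 11.3, "d36:2": 6.0}
      PS:   {"36:1": 30.0, "40:6": 25.0, "38:4": 15.0}
      PG:   {"34:1": 35.0, "36:2": 20.0}
      PC:   {"34:1": 32.0, "32:0": 18.0, "36:1": 15.0, "34:0": 10.0}
      Cer:  {"d42:1": 28.0, "d34:1": 22.0, "d36:1": 18.0}
      HexCer: {"d42:2": 30.0, "d42:1": 22.0, "d44:2": 12.0}
      DG:   {"34:1": 30.0, "36:2": 22.0, "38:4": 15.0}
  gbm_tmz:
    class_shares:
      negative: {PE: 0.33, PE_P: 0.20, PI: 0.216, PS: 0.103310,
                 PG: 0.036897, Sulf: 0.113793}
      positive: {PC: 0.40, SM: 0.36, HexCer: 0.12, Cer: 0.064, DG: 0.056}
    species_molpct:
      PE:   {"36:1": 30.0, "38:4": 13.4, "36:2": 10.1, "38:5": 8.0}
      PE_P: {"38:4": 22.0, "36:4": 14.8, "40:6": 10.4, "38:6": 10.3,
             "36:2": 3.6, "40:5": 4.3}
      PI:   {"38:4": 75.7}
      SM:   {"d34:1": 37.5, "d36:1": 26.6, "d36:2": 8.3}
      Sulf: {"d42:2": 23.9, "d36:3": 21.0, "d36:4": 11.4}
      PS:   {"36:1": 30.0, "40:6": 25.0, "38:4": 15.0}
      PG:   {"34:1": 35.0, "36:2": 20.0}
      PC:   {"34:1": 32.0, "32:0": 18.0, "36:1": 15.0, "34:0": 10.0}
      Cer:  {"d42:1": 28.0, "d34:1": 22.0, "d36:1": 18.0}
      HexCer: {"d42:2": 30.0, "d42:1": 22.0, "d44:2": 12.0}
      DG:   {"34:1": 30.0, "36:2": 22.0, "38:4": 15.0}
  bulk_parenchyma:
    class_shares:
      negative: {PE: 0.12, PE_P: 0.22, PI: 0.03, PS: 0.09, PG: 0.04, Sulf: 0.50}
      positive: {PC: 0.38, SM: 0.12, HexCer: 0.28, Cer: 0.12, DG: 0.10}
    species_molpct:
      PE:   {"40:6": 30.0, "38:4": 20.0, "36:1": 15.0}
      PE_P: {"40:6": 25.0, "38:4": 20.0, "34:1": 5.0}
      PI:   {"38:4": 40.0, "40:6": 15.0}
      PS:   {"40:6": 35.0, "36:1": 20.0}
      PG:   {"34:1": 30.0}
      Sulf: {"d42:2": 40.0, "t42:1": 20.0, "d44:2": 15.0}
      PC:   {"32:0": 20.0, "34:1": 30.0}
      SM:   {"d42:2": 35.0, "d36:1": 20.0}
      HexCer: {"d42:1": 30.0, "t42:1": 15.0}
      Cer:  {"d42:1": 30.0}
      DG:   {"34:1": 30.0}
noise:
  sigma: 0.3
  mz_jitter_ppm: 3
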