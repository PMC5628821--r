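waves:
- wave: 1
  min_spacing: 30
  oligos: 1
  design_floor: 0.8
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.2
- wave: 2
  min_spacing: 30
  oligos: 1
  design_floor: 0.8
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.1
- wave: 3
  min_spacing: 30
  oligos: 1
  design_floor: 0.8
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.05
- wave: 4
  min_spacing: 30
  oligos: 2
  design_floor: 0.8
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.05
- wave: 5
  min_spacing: 30
  oligos: 1
  design_floor: 0.7
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.2
- wave: 6
  min_spacing: 30
  oligos: 1
  design_floor: 0.7
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.1
- wave: 7
  min_spacing: 30
  oligos: 1
  design_floor: 0.7
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.05
- wave: 8
  min_spacing: 30
  oligos: 2
  design_floor: 0.7
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.05
- wave: 9
  min_spacing: 30
  oligos: 1
  design_floor: 0.7
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.2
- wave: 10
  min_spacing: 30
  oligos: 1
  design_floor: 0.7
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.1
- wave: 11
  min_spacing: 30
  oligos: 1
  design_floor: 0.7
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.05
- wave: 12
  min_spacing: 30
  oligos: 2
  design_floor: 0.7
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.05
- wave: 13
  min_spacing: 30
  oligos: 1
  design_floor: 0.6
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.2
- wave: 14
  min_spacing: 30
  oligos: 1
  design_floor: 0.6
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.1
- wave: 15
  min_spacing: 30
  oligos: 1
  design_floor: 0.6
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.05
- wave: 16
  min_spacing: 30
  oligos: 2
  design_floor: 0.6
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.05
- wave: 17
  min_spacing: 30
  oligos: 1
  design_floor: 0.6
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.2
- wave: 18
  min_spacing: 30
  oligos: 1
  design_floor: 0.6
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.1
- wave: 19
  min_spacing: 30
  oligos: 1
  design_floor: 0.6
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.05
- wave: 20
  min_spacing: 30
  oligos: 2
  design_floor: 0.6
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.05
- wave: 21
  min_spacing: 30
  oligos: 1
  design_floor: 0.8
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.0
- wave: 22
  min_spacing: 30
  oligos: 1
  design_floor: 0.7
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.0
- wave: 23
  min_spacing: 30
  oligos: 1
  design_floor: 0.7
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.0
- wave: 24
  min_spacing: 30
  oligos: 1
  design_floor: 0.6
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.0
- wave: 25
  min_spacing: 30
  oligos: 1
  design_floor: 0.6
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.0
- wave: 26
  min_spacing: 30
  oligos: 2
  design_floor: 0.8
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.0
- wave: 27
  min_spacing: 30
  oligos: 2
  design_floor: 0.7
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.0
- wave: 28
  min_spacing: 30
  oligos: 2
  design_floor: 0.7
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.0
- wave: 29
  min_spacing: 30
  oligos: 2
  design_floor: 0.6
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.0
- wave: 30
  min_spacing: 30
  oligos: 2
  design_floor: 0.6
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.0
- wave: 31
  min_spacing: 10
  oligos: 1
  design_floor: 0.8
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.2
- wave: 32
  min_spacing: 10
  oligos: 1
  design_floor: 0.8
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.1
- wave: 33
  min_spacing: 10
  oligos: 1
  design_floor: 0.8
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.05
- wave: 34
  min_spacing: 10
  oligos: 2
  design_floor: 0.8
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.05
- wave: 35
  min_spacing: 10
  oligos: 1
  design_floor: 0.7
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.2
- wave: 36
  min_spacing: 10
  oligos: 1
  design_floor: 0.7
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.1
- wave: 37
  min_spacing: 10
  oligos: 1
  design_floor: 0.7
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.05
- wave: 38
  min_spacing: 10
  oligos: 2
  design_floor: 0.7
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.05
- wave: 39
  min_spacing: 10
  oligos: 1
  design_floor: 0.7
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.2
- wave: 40
  min_spacing: 10
  oligos: 1
  design_floor: 0.7
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.1
- wave: 41
  min_spacing: 10
  oligos: 1
  design_floor: 0.7
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.05
- wave: 42
  min_spacing: 10
  oligos: 2
  design_floor: 0.7
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.05
- wave: 43
  min_spacing: 10
  oligos: 1
  design_floor: 0.6
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.2
- wave: 44
  min_spacing: 10
  oligos: 1
  design_floor: 0.6
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.1
- wave: 45
  min_spacing: 10
  oligos: 1
  design_floor: 0.6
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.05
- wave: 46
  min_spacing: 10
  oligos: 2
  design_floor: 0.6
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.05
- wave: 47
  min_spacing: 10
  oligos: 1
  design_floor: 0.6
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.2
- wave: 48
  min_spacing: 10
  oligos: 1
  design_floor: 0.6
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.1
- wave: 49
  min_spacing: 10
  oligos: 1
  design_floor: 0.6
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.05
- wave: 50
  min_spacing: 10
  oligos: 2
  design_floor: 0.6
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.05
- wave: 51
  min_spacing: 10
  oligos: 1
  design_floor: 0.8
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.0
- wave: 52
  min_spacing: 10
  oligos: 1
  design_floor: 0.7
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.0
- wave: 53
  min_spacing: 10
  oligos: 1
  design_floor: 0.7
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.0
- wave: 54
  min_spacing: 10
  oligos: 1
  design_floor: 0.6
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.0
- wave: 55
  min_spacing: 10
  oligos: 1
  design_floor: 0.6
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.0
- wave: 56
  min_spacing: 10
  oligos: 2
  design_floor: 0.8
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.0
- wave: 57
  min_spacing: 10
  oligos: 2
  design_floor: 0.7
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.0
- wave: 58
  min_spacing: 10
  oligos: 2
  design_floor: 0.7
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.0
- wave: 59
  min_spacing: 10
  oligos: 2
  design_floor: 0.6
  snp_floor: 100.0
  rule: per_breed
  maf_floor: 0.0
- wave: 60
  min_spacing: 10
  oligos: 2
  design_floor: 0.6
  snp_floor: 50.0
  rule: per_breed
  maf_floor: 0.0
- wave: 61
  min_spacing: 30
  oligos: 1
  design_floor: 0.6
  snp_floor: 50.0
  rule: n_breeds
  n_breeds: 3
- wave: 62
  min_spacing: 30
  oligos: 2
  design_floor: 0.6
  snp_floor: 50.0
  rule: n_breeds
  n_breeds: 3
- wave: 63
  min_spacing: 10
  oligos: 1
  design_floor: 0.6
  snp_floor: 50.0
  rule: n_breeds
  n_breeds: 3
- wave: 64
  min_spacing: 10
  oligos: 2
  design_floor: 0.6
  snp_floor: 50.0
  rule: n_breeds
  n_breeds: 3
- wave: 65
  min_spacing: 30
  oligos: 1
  design_floor: 0.6
  snp_floor: 50.0
  rule: n_breeds
  n_breeds: 2
- wave: 66
  min_spacing: 30
  oligos: 2
  design_floor: 0.6
  snp_floor: 50.0
  rule: n_breeds
  n_breeds: 2
- wave: 67
  min_spacing: 10
  oligos: 1
  design_floor: 0.6
  snp_floor: 50.0
  rule: n_breeds
  n_breeds: 2
- wave: 68
  min_spacing: 10
  oligos: 2
  design_floor: 0.6
  snp_floor: 50.0
  rule: n_breeds
  n_breeds: 2
- wave: 69
  min_spacing: 0
  oligos: 1
  design_floor: 0.0
  snp_floor: 0.0
  rule: catch_all
- wave: 70
  min_spacing: 0
  oligos: 2
  design_floor: 0.0
  snp_floor: 0.0
  rule: catch_all
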