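# Base-case model parameters: immediate vs delayed ranibizumab in nAMD,
# UK NHS perspective, cost year 2012, GBP. Printed rows carry rounding
# error; the loader renormalises each transition row proportionally.
version: "1.0"
states:
  labels:
    - "6/6 to >6/12"
    - "6/12 to 6/24"
    - "6/24 to 6/60"
    - "6/60 to 3/60"
    - "<3/60"
transitions:
  # single printed loading row (from best state, 3-month cycle)
  loading_row: [0.7240, 0.2222, 0.0335, 0.0108, 0.0096]
  # monthly cycle matrix under PRN treatment (months 3-24)
  monthly:
    - [0.8778, 0.1163, 0.0046, 0.0006, 0.0008]
    - [0.2937, 0.6243, 0.0783, 0.0032, 0.0005]
    - [0.0359, 0.2355, 0.6747, 0.0479, 0.0060]
    - [0.0219, 0.0146, 0.1533, 0.7007, 0.1095]
    - [0.0588, 0.0147, 0.0147, 0.2059, 0.7059]
utilities:
  # time trade-off utilities per acuity band: mean (sd)
  mean: [0.89, 0.81, 0.57, 0.52, 0.40]
  sd:   [0.16, 0.20, 0.17, 0.24, 0.12]
costs:
  drug_per_injection: 742.17
  assessment: 255.00
  monitoring: 60.00
  # expected PRN injections per post-loading month; calibrated so the
  # deterministic immediate-arm 2-year cost matches the reported total
  prn_injection_rate: 0.240
  drug_only: false
  sd_fraction: 0.10   # cost sd assumed 10% of mean for PSA
reentry:
  # state occupied on starting treatment in the delayed arm
  # (distribution of acuities at treatment initiation; renormalised)
  probabilities: [0.0, 0.434484, 0.3891544, 0.1456472, 0.0307501]
demographics:
  male:
    proportion: 0.365669
    age_mean: 78.8
    age_sd: 7.413      # from IQR 74-84 under a normal model
    age_min: 55
    age_max: 103
  female:
    proportion: 0.634331
    age_mean: 80.1
    age_sd: 7.413      # from IQR 76-86
    age_min: 55
    age_max: 108
mortality:
  # gender-specific Gompertz annual death probability q(a) = A * exp(B * a),
  # anchored to UK 2010-12 interim life table values at ages 65 and 85
  male:
    q65: 0.0143
    q85: 0.0998
  female:
    q65: 0.0087
    q85: 0.0726
  q_cap: 0.7
  age_range: [55, 110]
delay:
  # delayed arm: time from diagnosis to acuity dropping below 6/12
  family: exponential
  median_months: 6
horizon_months: 24
loading_months: 3
psa:
  effective_n: 100   # Dirichlet pseudo-count per transition row
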