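# Intervention-contrast presets for the total-PA survivor cohort network.
# Condition A is the less favorable state; deltas are mean(B) - mean(A).
# PA cut-points (270 / 380 counts/min/day) are fixed; sleep-impairment
# contrasts use marginal quartiles resolved at propagation time.
- label: "PA < 270 to >= 380"
  outcome: BMI
  condition_a:
    - {variable: PA, type: interval, hi: 270}
  condition_b:
    - {variable: PA, type: interval, lo: 380}
- label: "BMI >= 30 to < 30"
  outcome: loginsulin
  condition_a:
    - {variable: BMI, type: interval, lo: 30}
  condition_b:
    - {variable: BMI, type: interval, hi: 30}
- label: "BMI >= 30 to < 30"
  outcome: logcrp
  condition_a:
    - {variable: BMI, type: interval, lo: 30}
  condition_b:
    - {variable: BMI, type: interval, hi: 30}
- label: "BMI >= 30 to < 30"
  outcome: QOLp
  condition_a:
    - {variable: BMI, type: interval, lo: 30}
  condition_b:
    - {variable: BMI, type: interval, hi: 30}
- label: "BMI >= 30 to < 30"
  outcome: QOLm
  condition_a:
    - {variable: BMI, type: interval, lo: 30}
  condition_b:
    - {variable: BMI, type: interval, hi: 30}
- label: "Sleep2 > Q3 to < Q1"
  outcome: QOLp
  condition_a:
    - {variable: Sleep2, type: quantile, side: above, q: 0.75}
  condition_b:
    - {variable: Sleep2, type: quantile, side: below, q: 0.25}
- label: "Sleep2 > Q3 to < Q1"
  outcome: QOLm
  condition_a:
    - {variable: Sleep2, type: quantile, side: above, q: 0.75}
  condition_b:
    - {variable: Sleep2, type: quantile, side: below, q: 0.25}
- label: "Sleep2 > Q3 & BMI >= 30 to Sleep2 < Q1 & BMI < 30"
  outcome: QOLp
  condition_a:
    - {variable: Sleep2, type: quantile, side: above, q: 0.75}
    - {variable: BMI, type: interval, lo: 30}
  condition_b:
    - {variable: Sleep2, type: quantile, side: below, q: 0.25}
    - {variable: BMI, type: interval, hi: 30}
- label: "Sleep2 > Q3 & BMI >= 30 to Sleep2 < Q1 & BMI < 30"
  outcome: QOLm
  condition_a:
    - {variable: Sleep2, type: quantile, side: above, q: 0.75}
    - {variable: BMI, type: interval, lo: 30}
  condition_b:
    - {variable: Sleep2, type: quantile, side: below, q: 0.25}
    - {variable: BMI, type: interval, hi: 30}
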