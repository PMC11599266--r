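# Worked configuration: trifluridine/tipiracil + bevacizumab vs
# trifluridine/tipiracil monotherapy, third-line colorectal cancer,
# Chinese healthcare-system perspective. Costs in 2023 CNY, time in months.
schema_version: 1
model:
  cycle_days: 28
  horizon_years: 10
  annual_discount: {baseline: 0.05, low: 0.00, high: 0.08, distribution: beta}
  wtp: 268200.00            # 3x 2023 Chinese per-capita GDP, CNY/QALY
  half_cycle_correction: false
  transition_mode: markov
strategies:
  - name: FTD-TPI plus bevacizumab
    drug_cost_per_cycle: {baseline: 23625.40, low: 18900.32, high: 28350.48, distribution: gamma}
    survival:
      os:  {family: lognormal, shape: 2.398, scale: 0.808}
      pfs: {family: lognormal, shape: 1.660, scale: 0.850}
    adverse_events:           # grade >= 3 incidences, per patient
      - {name: neutropenia, incidence: 0.431}
      - {name: nausea, incidence: 0.016}
      - {name: anemia, incidence: 0.061}
      - {name: fatigue, incidence: 0.041}
      - {name: tiredness, incidence: 0.012}
      - {name: diarrhea, incidence: 0.008}
      - {name: decreased_appetite, incidence: 0.008}
  - name: FTD-TPI
    drug_cost_per_cycle: {baseline: 13947.40, low: 11157.92, high: 16736.88, distribution: gamma}
    survival:
      os:  {family: lognormal, shape: 2.030, scale: 0.793}
      pfs: {family: lognormal, shape: 1.110, scale: 0.644}
    adverse_events:
      - {name: neutropenia, incidence: 0.321}
      - {name: nausea, incidence: 0.016}
      - {name: anemia, incidence: 0.110}
      - {name: fatigue, incidence: 0.041}
costs:
  lab_per_visit:        {baseline: 317.36, low: 253.89, high: 380.83, distribution: gamma}
  imaging_per_visit:    {baseline: 677.70, low: 542.16, high: 813.24, distribution: gamma}
  end_of_life_once:     {baseline: 11299.00, low: 9039.20, high: 13558.80, distribution: gamma}
  supportive_per_cycle: {baseline: 2141.20, low: 1712.96, high: 2569.44, distribution: gamma}
  # published upper limit misprinted as "9.49.32"; 9049.32 (= 1.2x baseline)
  # restores the +-20% convention used for every other cost row
  subsequent_tx_per_cycle: {baseline: 7541.10, low: 6032.88, high: 9049.32, distribution: gamma}
ae_unit_costs:          # CNY per managed event
  neutropenia:        {baseline: 3214.90, low: 2571.92, high: 3857.88, distribution: gamma}
  nausea:             {baseline: 298.00, low: 238.40, high: 357.60, distribution: gamma}
  anemia:             {baseline: 531.00, low: 424.80, high: 637.20, distribution: gamma}
  fatigue:            {baseline: 20.80, low: 16.64, high: 24.96, distribution: gamma}
  tiredness:          {baseline: 293.01, low: 234.41, high: 351.61, distribution: gamma}
  diarrhea:           {baseline: 276.00, low: 220.80, high: 331.20, distribution: gamma}
  decreased_appetite: {baseline: 705.40, low: 564.32, high: 846.48, distribution: gamma}
utilities:
  u_pfs: {baseline: 0.84, low: 0.67, high: 1.00, distribution: beta}
  u_pd:  {baseline: 0.57, low: 0.46, high: 0.68, distribution: beta}
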