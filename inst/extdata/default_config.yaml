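# Default model configuration: base-case inputs for the cost-utility
# comparison of ezetimibe + moderate-intensity statin vs moderate-intensity
# statin alone for secondary prevention after ACS (Thailand, 2024 THB).
# Every value can be overridden by a user configuration; omitted keys fall
# back to these defaults.
metadata:
  description: >
    Base-case inputs: annual event probabilities per arm, post-event annual
    case fatality, post-ACS excess-mortality hazard ratio (stored as log
    HR), ezetimibe relative risks of death, annual costs in 2024 THB,
    utilities and utility decrements, each with its 95% interval and
    probabilistic distribution family.
  currency: THB (2024)
  statin_daily_cost_thb: 0.80    # simvastatin 40 mg, median across brands
  ezetimibe_daily_cost_thb: 4.74 # ezetimibe 10 mg, median across brands
  days_per_year: 365

settings:
  start_age: 62
  cycle_length: 1
  max_age: 100
  discount_rate_costs: 0.03
  discount_rate_outcomes: 0.03
  wtp: 160000
  perspective: societal
  psa_iterations: 1000
  rng_seed: 1
  half_cycle: true
  timing_offset: 0.5
  exchange_rate_thb_per_usd: 35.2952
  post_event_mortality: event_only
  first_year_cost_basis: cycle1
  acs_cost_states: no_event_only

parameters:
  # --- moderate-intensity statin alone: annual event probabilities
  p_mi_statin:     {base: 0.016900, low: 0.0152, high: 0.0186, distribution: beta, role: probability}
  p_stroke_statin: {base: 0.005415, low: 0.0049, high: 0.0060, distribution: beta, role: probability}
  # --- annual probability of death while in a post-event state (both arms)
  p_death_mi:      {base: 0.090263, low: 0.0812, high: 0.0993, distribution: beta, role: probability}
  p_death_stroke:  {base: 0.071593, low: 0.0644, high: 0.0788, distribution: beta, role: probability}
  # --- ezetimibe + moderate-intensity statin: annual event probabilities
  p_mi_ez:         {base: 0.014779, low: 0.0133, high: 0.0163, distribution: beta, role: probability}
  p_stroke_ez:     {base: 0.004653, low: 0.0042, high: 0.0051, distribution: beta, role: probability}
  # --- mortality adjustments; log_hr_excess is ln(HR), HR = 2.0 for
  #     post-ACS excess background mortality; interval on the log scale
  log_hr_excess:   {base: 0.693, low: 0.62, high: 0.76, distribution: lognormal, role: log_hazard_ratio}
  rr_death_mi:     {base: 0.840, low: 0.55, high: 1.07, distribution: lognormal, role: relative_risk}
  rr_death_stroke: {base: 0.900, low: 0.84, high: 0.96, distribution: lognormal, role: relative_risk}
  rr_death_any:    {base: 0.990, low: 0.91, high: 1.07, distribution: lognormal, role: relative_risk}
  # --- annual drug costs, THB (daily price x 365)
  cost_statin_annual: {base: 292,  low: 234,  high: 350,  distribution: gamma, role: cost_THB_per_year}
  cost_ez_annual:     {base: 1730, low: 1384, high: 2075, distribution: gamma, role: cost_THB_per_year}
  # --- treatment costs, THB per year
  cost_acs_y1:        {base: 65507,  low: 45174,  high: 67762,  distribution: gamma, role: cost_THB_per_year}
  cost_acs_y2plus:    {base: 39617,  low: 27320,  high: 40980,  distribution: gamma, role: cost_THB_per_year}
  cost_mi_y1:         {base: 148366, low: 102314, high: 153472, distribution: gamma, role: cost_THB_per_year}
  cost_mi_y2plus:     {base: 15924,  low: 10982,  high: 16472,  distribution: gamma, role: cost_THB_per_year}
  cost_stroke_y1:     {base: 73440,  low: 50645,  high: 75967,  distribution: gamma, role: cost_THB_per_year}
  cost_stroke_y2plus: {base: 11634,  low: 8023,   high: 12035,  distribution: gamma, role: cost_THB_per_year}
  # --- direct non-medical costs (societal perspective only)
  cost_dnm_y1:        {base: 3730, low: 2572, high: 3858, distribution: gamma, role: cost_THB_per_year}
  cost_dnm_y2plus:    {base: 5394, low: 3720, high: 5580, distribution: gamma, role: cost_THB_per_year}
  # --- utilities
  u_acs:      {base: 0.82,    low: 0.738,  high: 0.902,  distribution: beta,  role: utility}
  dec_mi:     {base: 0.41635, low: 0.3747, high: 0.4580, distribution: gamma, role: utility_decrement}
  dec_stroke: {base: 0.2259,  low: 0.2033, high: 0.2485, distribution: gamma, role: utility_decrement}
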