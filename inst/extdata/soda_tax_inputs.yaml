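# Default model inputs for the California soda-tax cost-effectiveness model.
# All monetary values are 2022 USD. uncertainty: one of ci95 (a printed 95%
# interval), pm25 (plus/minus 25% of the value; bounds may be omitted and are
# then derived), fixed (no uncertainty). family: PSA sampling distribution.
config:
  n_individuals: 20000
  horizon_years: 20
  discount_rate: 0.03
  rescale_factor: 1462.36
  wtp: 100000
  calories_per_gram_sugar: 4
  kcal_per_pound: 3500
  lb_per_kg: 2.20462
  days_per_year: 365
  admin_cost_fraction: 0.01

weight:
  natural_gain_kg_per_year: {low: 0.45, high: 0.91}
  tax_weight_effect_kg_per_year:
    {mean: -0.56, low: -1.93, high: 0.77, uncertainty: ci95, family: normal}

revenue:
  annual_tax_revenue_usd:
    {mean: 862722888, uncertainty: pm25, family: gamma}
  admin_cost_usd_per_year:
    {mean: 8627229, uncertainty: pm25, family: gamma}

# Annual direct medical cost per person occupying each state.
costs:
  normal:     {mean: 0, uncertainty: fixed}
  overweight: {mean: 1320,   low: 1069,   high: 1607,   uncertainty: ci95, family: gamma}
  obesity:    {mean: 3955,   low: 3519,   high: 4363,   uncertainty: ci95, family: gamma}
  diabetes:   {mean: 21218,  low: 15913,  high: 26522,  uncertainty: pm25, family: gamma}
  stroke:     {mean: 103425, low: 77569,  high: 129281, uncertainty: pm25, family: gamma}
  poststroke: {mean: 38159,  low: 28619,  high: 47698,  uncertainty: pm25, family: gamma}
  mi:         {mean: 138603, low: 103952, high: 173253, uncertainty: pm25, family: gamma}
  postmi:     {mean: 4675,   low: 3506,   high: 5843,   uncertainty: pm25, family: gamma}
  esrd:       {mean: 176647, low: 132485, high: 220808, uncertainty: pm25, family: gamma}

# EQ-5D utility per state-year. Stroke covers poststroke, MI covers post-MI.
utilities:
  normal:     {mean: 1,     low: 0.75,  high: 1,     uncertainty: pm25, family: beta}
  overweight: {mean: 0.876, low: 0.657, high: 1,     uncertainty: pm25, family: beta}
  obesity:    {mean: 0.850, low: 0.637, high: 1,     uncertainty: pm25, family: beta}
  diabetes:   {mean: 0.785, low: 0.681, high: 0.889, uncertainty: ci95, family: beta}
  stroke:     {mean: 0.621, low: 0.459, high: 0.784, uncertainty: ci95, family: beta}
  mi:         {mean: 0.730, low: 0.614, high: 0.847, uncertainty: ci95, family: beta}
  esrd:       {mean: 0.61,  low: 0.51,  high: 0.71,  uncertainty: ci95, family: beta}
  death:      {mean: 0, uncertainty: fixed}

# Annual transition probabilities; residual mass is the stay probability.
transitions:
  - {origin: normal,     destination: diabetes, mean: 0.0069, low: 0.0058, high: 0.0083, uncertainty: ci95, family: beta}
  - {origin: normal,     destination: stroke,   mean: 0.0028, low: 0.0025, high: 0.0032, uncertainty: ci95, family: beta}
  - {origin: normal,     destination: mi,       mean: 0.0028, low: 0.0025, high: 0.0033, uncertainty: ci95, family: beta}
  - {origin: normal,     destination: esrd,     mean: 0.0004, low: 0.0003, high: 0.0005, uncertainty: pm25, family: beta}
  - {origin: normal,     destination: death,    mean: 0.0090, low: 0.0067, high: 0.0112, uncertainty: pm25, family: beta}
  - {origin: overweight, destination: diabetes, mean: 0.0088, low: 0.0084, high: 0.0092, uncertainty: ci95, family: beta}
  - {origin: overweight, destination: stroke,   mean: 0.0029, low: 0.0027, high: 0.0033, uncertainty: ci95, family: beta}
  - {origin: overweight, destination: mi,       mean: 0.0033, low: 0.0028, high: 0.0039, uncertainty: ci95, family: beta}
  - {origin: overweight, destination: esrd,     mean: 0.0005, low: 0.0005, high: 0.0006, uncertainty: ci95, family: beta}
  - {origin: overweight, destination: death,    mean: 0.0087, low: 0.0087, high: 0.0087, uncertainty: fixed}
  - {origin: obesity,    destination: diabetes, mean: 0.0135, low: 0.0119, high: 0.0154, uncertainty: ci95, family: beta}
  - {origin: obesity,    destination: stroke,   mean: 0.0035, low: 0.0032, high: 0.0039, uncertainty: ci95, family: beta}
  - {origin: obesity,    destination: mi,       mean: 0.0044, low: 0.0034, high: 0.0055, uncertainty: ci95, family: beta}
  - {origin: obesity,    destination: esrd,     mean: 0.0007, low: 0.0006, high: 0.0008, uncertainty: ci95, family: beta}
  - {origin: obesity,    destination: death,    mean: 0.0118, low: 0.0117, high: 0.0119, uncertainty: ci95, family: beta}
  - {origin: diabetes,   destination: stroke,   mean: 0.0042, low: 0.0032, high: 0.0057, uncertainty: ci95, family: beta}
  - {origin: diabetes,   destination: mi,       mean: 0.0051, low: 0.0038, high: 0.0067, uncertainty: ci95, family: beta}
  - {origin: diabetes,   destination: esrd,     mean: 0.0023, low: 0.0022, high: 0.0024, uncertainty: ci95, family: beta}
  - {origin: diabetes,   destination: death,    mean: 0.0128, low: 0.0120, high: 0.0137, uncertainty: ci95, family: beta}
  - {origin: stroke,     destination: mi,       mean: 0.03,   low: 0.01,   high: 0.05,   uncertainty: ci95, family: beta}
  - {origin: stroke,     destination: death,    mean: 0.17,   low: 0.13,   high: 0.21,   uncertainty: pm25, family: beta}
  - {origin: mi,         destination: stroke,   mean: 0.081,  low: 0.061,  high: 0.101,  uncertainty: pm25, family: beta}
  - {origin: mi,         destination: death,    mean: 0.22,   low: 0.16,   high: 0.27,   uncertainty: pm25, family: beta}
  - {origin: esrd,       destination: stroke,   mean: 0.0172, low: 0.0146, high: 0.0200, uncertainty: ci95, family: beta}
  - {origin: esrd,       destination: mi,       mean: 0.0040, low: 0.0032, high: 0.0050, uncertainty: ci95, family: beta}
  - {origin: esrd,       destination: death,    mean: 0.034,  low: 0.025,  high: 0.042,  uncertainty: pm25, family: beta}
  - {origin: poststroke, destination: mi,       mean: 0.0167, low: 0.0136, high: 0.0198, uncertainty: ci95, family: beta}
  - {origin: poststroke, destination: death,    mean: 0.0173, low: 0.0119, high: 0.0235, uncertainty: ci95, family: beta}
  - {origin: postmi,     destination: stroke,   mean: 0.0087, low: 0.0083, high: 0.0092, uncertainty: ci95, family: beta}
  - {origin: postmi,     destination: death,    mean: 0.21,   low: 0.16,   high: 0.26,   uncertainty: pm25, family: beta}
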