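# Codebook for the synthetic example survey (example_survey.csv): maps the
# package's canonical field names to the survey's column names, declares the
# asset indicator columns and their 0/1 coding, and fixes the exchange rate
# used to convert the local-currency income to USD.
columns:
  household_id: hhid
  site: community
  haz: zlen
  child_age_months: age_months
  child_sex: sex
  maternal_education_years: mom_school
  income_local: income
  currency: cur
  people_per_room: crowding
  improved_water: water
  improved_sanitation: toilet
  any_child_died: died
  electricity: elec
  natural_flooring: floor
  solid_cooking_fuel: fuel
assets:
  radio: has_radio
  tv: has_tv
  fridge: has_fridge
  mobile_phone: has_mobile
indicator_coding:
  "yes": 1
  "no": 0
currency_table:
  date: "2010-01-01"
  rates:
    XTS: 0.02
    USD: 1.0
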