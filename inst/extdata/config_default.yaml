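# Example run configuration. The limits block is a per-capita placeholder
# chart (daily 5 g salt, 30 g sugar, 30 ml oil per person, x 30 days);
# deployments should replace it with their locally recommended chart.
limits:
  - {household_size: 1, salt_g_30d: 150, sugar_g_30d: 900, oil_ml_30d: 900}
  - {household_size: 2, salt_g_30d: 300, sugar_g_30d: 1800, oil_ml_30d: 1800}
  - {household_size: 3, salt_g_30d: 450, sugar_g_30d: 2700, oil_ml_30d: 2700}
  - {household_size: 4, salt_g_30d: 600, sugar_g_30d: 3600, oil_ml_30d: 3600}
  - {household_size: 5, salt_g_30d: 750, sugar_g_30d: 4500, oil_ml_30d: 4500}
  - {household_size: 6, salt_g_30d: 900, sugar_g_30d: 5400, oil_ml_30d: 5400}
  - {household_size: 7, salt_g_30d: 1050, sugar_g_30d: 6300, oil_ml_30d: 6300}
  - {household_size: 8, salt_g_30d: 1200, sugar_g_30d: 7200, oil_ml_30d: 7200}
policies:
  fv_daily_rule: both    # both | either
  sso_rule: all          # all | any
  fruit_target: 2
  veg_target: 3
  missing: strict        # strict | lenient
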