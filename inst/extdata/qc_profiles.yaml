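# Named QC profiles. Discovery profiles use inclusive genotype thresholds
# ("a minimum genotype quality of 10" admits GQ = 10); the replication
# profile uses strict inequalities ("greater than 25" rejects GQ = 25).
# Site quality is always strictly greater-than on the scheme-matched scale.
discovery_sayo:
  min_gq: 10
  min_ad_alt: 2
  min_dp: 7
  min_ab: 0.1
  min_site_quality_vqslod: 2
  min_site_quality_qual: 38
  af_max: 1.0e-4
  strict: false
discovery_spark:
  min_gq: 10
  min_ad_alt: 2
  min_dp: 7
  min_ab: 0.1
  min_site_quality_vqslod: 2
  min_site_quality_qual: 38
  af_max: 1.0e-4
  strict: false
replication_ukbb:
  min_gq: 25
  min_ad_alt: 3
  min_dp: 10
  min_ab: 0.2
  min_site_quality_vqslod: 2
  min_site_quality_qual: 38
  af_max: 1.0e-4
  strict: true
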