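# Default feed-intake curve sets, one per production stage and performance
# stratum. Values are sampled daily-intake points (kg feed/day against days
# on feed); the package fits a least-squares polynomial (degree below) to
# the points and integrates the fit analytically to obtain cumulative feed.
# These defaults are calibrated to plausible commercial magnitudes only and
# are intended to be swapped for herd- or calculator-specific curves.
creep:
  # Total litter creep intake (g) as a polynomial in creep-feeding duration
  # (days), ascending coefficients, normalized to a standard litter of 11.
  litter_size_standard: 11
  coefficients: [0.0, 20.0, 6.0]
degree: 2
nursery:
  low:
    days: [0, 13, 26, 39, 52, 65, 78, 91]
    intake_kg: [0.13, 0.32, 0.52, 0.72, 0.93, 1.14, 1.36, 1.58]
  average:
    days: [0, 13, 26, 39, 52, 65, 78, 91]
    intake_kg: [0.15, 0.38, 0.62, 0.85, 1.10, 1.35, 1.61, 1.87]
  high:
    days: [0, 13, 26, 39, 52, 65, 78, 91]
    intake_kg: [0.17, 0.43, 0.69, 0.96, 1.24, 1.52, 1.81, 2.10]
grower_finisher:
  low:
    days: [0, 28, 56, 84, 112, 140, 160]
    intake_kg: [0.90, 1.50, 2.05, 2.50, 2.85, 3.10, 3.20]
  average:
    days: [0, 28, 56, 84, 112, 140, 160]
    intake_kg: [1.00, 1.70, 2.35, 2.85, 3.20, 3.45, 3.55]
  high:
    days: [0, 28, 56, 84, 112, 140, 160]
    intake_kg: [1.10, 1.90, 2.60, 3.15, 3.55, 3.80, 3.90]
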