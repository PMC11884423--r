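# Alopecia areata seamless phase II/III trial (placebo, three active dose
# groups; selection of the highest dose at the interim analysis based on the
# week-12 short-term response; week-36 long-term response compared at the
# final analysis). Interim information fraction ~ 0.12.
#
# Published quantities: stage sizes, stage-1 short-term counts (3, 5, 8, 9),
# and the pooled long-term totals Y0/N0 = 10/189, Ys/Ns = 99/281.
#
# Reconstructed (synthetic) quantities, needed to complete the record:
#   * stage-2 short-term counts assume the stage-2 response rate equals the
#     stage-1 rate in each continued group;
#   * the stage split of the long-term totals is proportional to the stage
#     sizes;
#   * dual-responder counts are set so the per-group Pearson correlation of
#     the two endpoints is approximately 0.6.
# Analyses that use only the long-term totals (the pooled MLE of the
# long-term probabilities) are unaffected by the reconstruction.
G: 3
n1: [28, 28, 27, 27]
n2: [161, 0, 0, 254]
s: 3
x1: [3, 5, 8, 9]
y1: [1, ~, ~, 10]
z1: [1, ~, ~, 7]
x2: [17, ~, ~, 85]
y2: [9, ~, ~, 89]
z2: [8, ~, ~, 64]
level: 0.025
conf: 0.95
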