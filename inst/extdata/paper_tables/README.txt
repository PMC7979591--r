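Published cross-classification counts of liver iron burden under pairs of
LIC calibration equations, transcribed from the source study's agreement
tables. Orientation: rows index the first-named calibration of the file
name, columns the second (the published EASL tables are printed in the
transposed orientation; percent agreement and Cohen's kappa are invariant
under transposition). yesno_* files are the binary pathologic-iron call
(LIC > 36 umol/g); easl_* files are the four-group severity grading.
printed_stats.csv carries the published overall agreement percentages and
unweighted kappas (with their published standard errors) for comparison.
n = 386 in every table.
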