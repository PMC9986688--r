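# Published calibration parameters for breast-cancer PRSs, estimated on a
# large European case-control consortium dataset (~22,800 controls,
# ~16,200 invasive cases, ages < 80).  alpha_glm: transformed-covariate
# logistic regression; alpha_rl: retrospective likelihood;
# predicted_alpha_rl: proportionality calibration 0.887 * log_or_per_sd.
prs,n_snps,mean_controls,mean_cases,sd_controls,sd_cases,log_or_per_sd,alpha_glm,alpha_rl,ratio_rl_to_lor,predicted_alpha_rl,chek2_snps_excluded
BCAC PRS313,313,-0.424,-0.114,0.611,0.619,0.497,0.397,0.441,0.887,0.441,0
BRIDGES,306,-0.422,-0.114,0.608,0.615,0.495,0.394,0.439,0.886,0.439,0
PERSPECTIVE,295,-0.448,-0.147,0.599,0.609,0.489,0.389,0.433,0.886,0.434,0
EASTGLH,303,-0.407,-0.100,0.606,0.613,0.494,0.394,0.438,0.886,0.438,0
PRISMA,268,0.322,0.575,0.558,0.565,0.446,0.358,0.396,0.890,0.395,0
eMERGE,308,-0.456,-0.150,0.608,0.616,0.495,0.394,0.439,0.887,0.439,0
DBDS299,299,-0.508,-0.211,0.596,0.605,0.486,0.387,0.432,0.888,0.431,0
BCAC PRS77,77,-0.892,-0.703,0.449,0.460,0.394,0.310,0.350,0.889,0.349,0
BCAC PRS3820,3820,-0.445,-0.199,0.460,0.463,0.518,0.412,0.454,0.878,0.459,0
WISDOM75,74,-1.057,-0.835,0.567,0.573,0.360,0.281,0.315,0.875,0.319,0
WISDOM128,126,-0.180,0.041,0.464,0.478,0.449,0.355,0.402,0.895,0.398,0
BCAC PRS311,311,-0.092,0.217,0.609,0.618,0.496,0.395,0.439,0.886,0.440,1
BRIDGES ex-CHEK2,305,-0.428,-0.121,0.607,0.615,0.495,0.394,0.438,0.886,0.439,1
PERSPECTIVE ex-CHEK2,293,-0.116,0.183,0.598,0.607,0.488,0.388,0.432,0.885,0.433,1
EASTGLH ex-CHEK2,301,-0.075,0.230,0.604,0.612,0.492,0.392,0.436,0.885,0.437,1
eMERGE ex-CHEK2,306,-0.124,0.181,0.606,0.614,0.493,0.393,0.437,0.886,0.437,1
DBDS299 ex-CHEK2,297,-0.177,0.119,0.594,0.603,0.485,0.386,0.430,0.887,0.430,1
BCAC PRS3818,3818,-0.227,0.018,0.459,0.462,0.517,0.411,0.453,0.877,0.458,1
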