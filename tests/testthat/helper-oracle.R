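# Frozen reference solutions for the three CFA fixtures under extdata/.
# Computed once by an independent ML-CFA implementation (numpy/scipy:
# natural-scale box-constrained L-BFGS-B, numerical gradients,
# finite-difference Hessian) fed the same CSV files; its own coding of the
# standard fit-index formulas produced the index values.
oracle_fixtures <- list(
  onefactor = list(
    chisq = 8.837375276e-14, df = 0, fmin = 4.4408920985e-16,
    chisq_baseline = 146.2344154, df_baseline = 3,
    cmin_df = NA_real_, gfi = 1, cfi = 1,
    tli = NA_real_, rmsea = NA_real_, srmr = 1.326494026e-08,
    estimates = c(0.8651110088, 0.5638492245, 0.9858711418, 0.4564542925, 0.6500670624, 0.6613298852),
    se = c(0.1253796191, 0.08793269916, 0.1861626258, 0.1339287583, 0.1145477253, 0.07743968397),
    std_first = c(0.8267580763, 0.7291238224, 0.5670525993)
  ),
  twofactor = list(
    chisq = 6.219547139, df = 8, fmin = 0.0312540057214,
    chisq_baseline = 273.7966491, df_baseline = 15,
    cmin_df = 0.7774433923, gfi = 0.9898897395, cfi = 1,
    tli = 1.012899507, rmsea = 0, srmr = 0.02646857861,
    estimates = c(0.6364420346, 0.4554565998, 0.9513070688, 0.3561733244, 1.096729716, 0.510325247, 1.429219433, 0.4119839658, 0.6717230803, 0.6555772696, 0.9626158831, 0.6105788955, 0.8232860648),
    se = c(0.1075889988, 0.08647353759, 0.1454372661, 0.0686239165, 0.2158967807, 0.1312650748, 0.2960765779, 0.1647620896, 0.09475108438, 0.07579063151, 0.2208864334, 0.1882228796, 0.08752758174),
    std_first = c(0.8526020864, 0.6309338306, 0.5075699231, 0.7730076988, 0.8242075081, 0.4248299397)
  ),
  secondorder = list(
    chisq = 19.07958428, df = 24, fmin = 0.0638113186711,
    chisq_baseline = 690.244967, df_baseline = 36,
    cmin_df = 0.7949826784, gfi = 0.9865803521, cfi = 1,
    tli = 1.011281132, rmsea = 0, srmr = 0.03081389415,
    estimates = c(0.803264041, 0.6139411329, 0.5275238588, 0.8545283199, 0.3891611869, 0.6277941591, 0.701528185, 0.6172094124, 0.743572009, 0.4045867248, 0.6043493763, 0.8298248418, 0.5516607951, 0.5347641251, 0.7153199029, 0.3624127633, 0.6112845355, 0.7353236697, 0.4501321947, 0.681053345, 0.9220471486),
    se = c(0.083036432, 0.07495751464, 0.06327012299, 0.08871394485, 0.0577975273, 0.0831298325, 0.09196078602, 0.08525555282, 0.1011191129, 0.1234233407, 0.1228026066, 0.1925993037, 0.08964249302, 0.06673656097, 0.06837846274, 0.0886412768, 0.05653864434, 0.08670954229, 0.1559674955, 0.06134070266, 0.09786364844),
    std_first = c(0.7868425461, 0.7208923417, 0.5664706838, 0.8550379348, 0.5564647524, 0.7032463603, 0.8685674729, 0.4849417837, 0.6094918707),
    std_second = c(0.7408233001, 0.6217975357, 0.6323466978)
  )
)

fixture_path <- function(name)
  system.file("extdata", paste0("cfa_fixture_", name, ".csv"),
              package = "iitqa", mustWork = TRUE)

fixture_models <- function() list(
  onefactor = cfa_model(list(f1 = c("y1", "y2", "y3")), second_order = FALSE),
  twofactor = cfa_model(list(f1 = c("y1", "y2", "y3"),
                             f2 = c("y4", "y5", "y6")), second_order = FALSE),
  secondorder = cfa_model(list(f1 = paste0("y", 1:3), f2 = paste0("y", 4:6),
                               f3 = paste0("y", 7:9)), second_order = TRUE))
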