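test_that("every recomputed summary cell matches outside the known misprint", {
  cells <- table_regression()
  ok <- cells[!cells$known_misprint, ]
  expect_true(all(ok$match))
  # the two flagged cells are a transcription defect in the source table:
  # both CI bounds of the patient experimental ICP are printed as the mean
  bad <- cells[cells$known_misprint, ]
  expect_equal(nrow(bad), 2)
  expect_setequal(bad$statistic, c("ci_lower", "ci_upper"))
  expect_equal(unique(bad$variable), "experimental_ICP_SAS")
  expect_false(any(bad$match))
})

test_that("claims_report recomputes all 20 in-text claims with categories", {
  cr <- claims_report()
  expect_s3_class(cr, "csf_claims")
  expect_equal(nrow(cr), 20)
  expect_setequal(unique(cr$category), c("hard", "borderline", "discordant"))
  # every hard claim passes at one unit in the last printed digit
  expect_true(all(cr$pass[cr$category == "hard"]))
  # the BC-A ICP agreement sits exactly on a rounding boundary
  expect_equal(cr$claim[cr$category == "borderline"], "icp_agreement_BC_A_pct")
  # the correlation-based claims do not reproduce from the table rows
  expect_setequal(cr$claim[cr$category == "discordant"],
                  c("pcc_BC_A", "pcc_BC_B", "pcc_BC_C",
                    "pcc_reduction_BC_A_pct", "pcc_reduction_BC_B_pct"))
  expect_false(any(cr$pass[cr$category == "discordant"]))
  # every claim documents its inputs
  expect_true(all(nchar(cr$inputs) > 0))
})

test_that("hard claims match their printed values within one printed unit", {
  cr <- claims_report()
  chk <- function(id, printed) {
    row <- cr[cr$claim == id, ]
    expect_equal(row$printed, printed)
    # the package's matching rule: round-half-up at the printed precision,
    # then at most one unit in the last printed digit
    expect_lte(abs(round_half_up(row$recomputed, row$digits) - printed),
               10^(-row$digits) + 1e-9)
  }
  chk("ventricular_volume_ratio", 13.9)
  chk("brain_volume_reduction_pct", 17.4)
  chk("sas_volume_increase_pct", 2.4)
  chk("sas_pressure_ratio_BC_A", 5.5)
  chk("sas_pressure_ratio_BC_B", 5.1)
  chk("sas_pressure_ratio_BC_C", 5.1)
  chk("ca_pressure_ratio_BC_A", 5.7)
  chk("reynolds_group_diff_BC_A_pct", 16.9)
  chk("reynolds_group_diff_BC_B_pct", 15.8)
  chk("reynolds_group_diff_BC_C_pct", 15.7)
  chk("icp_agreement_BC_B_pct", 14.1)
  chk("icp_agreement_BC_C_pct", 4.6)
})

test_that("reproduce_claims combines cells and claims into one verdict", {
  out <- tempfile(fileext = ".json"); on.exit(unlink(out))
  rep <- reproduce_claims(out = out)
  expect_s3_class(rep, "csf_reproduction")
  expect_true(rep$ok)
  expect_equal(rep$n_cells_checked, sum(!rep$cells$known_misprint))
  expect_true(file.exists(out))
  js <- jsonlite::read_json(out)
  expect_true(js$ok)
  expect_true(length(js$manifest$input_digests) >= 4)
  # glance gives the one-row audit summary
  g <- glance(rep)
  expect_true(g$ok)
  expect_equal(g$n_hard, g$n_hard_pass)
})

test_that("reproduction is deterministic", {
  a <- claims_report(); b <- claims_report()
  expect_equal(a$recomputed, b$recomputed)
})
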