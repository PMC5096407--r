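# Executable identification key

test_that("the packaged key is structurally sound", {
  rep <- validate_key()
  expect_s3_class(rep, "key_report")
  expect_true(rep$acyclic)
  expect_true(rep$all_reachable)
  expect_equal(rep$n_species, 17L)
})

test_that("complete observations identify single species", {
  pallida <- identify_specimen(list(
    flanges_serrated = TRUE, serrations_along_most = TRUE,
    radiolar_eyes = FALSE, serration_pairs = 6, dark_bands = FALSE,
    tooth_rows = 3))
  expect_equal(pallida$taxa, "Pseudobranchiomma pallida")
  orientalis <- identify_specimen(list(
    flanges_serrated = TRUE, serrations_along_most = TRUE,
    radiolar_eyes = FALSE, serration_pairs = 25, thoracic_chaetigers = 8,
    tooth_rows = 7))
  expect_equal(orientalis$taxa, "Pseudobranchiomma orientalis")
})

test_that("empty observations reach all 17 valid species", {
  res <- identify_specimen(list())
  expect_equal(length(res$taxa), 17L)
  expect_gt(length(res$ambiguous_at), 0L)
})

test_that("eye-bearing serrated specimens hit the cautioned couplet", {
  res <- identify_specimen(list(flanges_serrated = TRUE,
                                serrations_along_most = TRUE,
                                radiolar_eyes = TRUE))
  expect_setequal(res$taxa, c("Pseudobranchiomma grandis",
                              "Pseudobranchiomma serratibranchis"))
  expect_gt(length(res$cautions), 0L)
})

test_that("contradictory observations raise a no-path error naming the couplet", {
  err <- tryCatch(identify_specimen(list(
    flanges_serrated = TRUE, serrations_along_most = TRUE,
    radiolar_eyes = FALSE, serration_pairs = 9, dark_bands = FALSE,
    tooth_rows = 9)), error = identity)
  expect_s3_class(err, "key_no_path_error")
  expect_match(conditionMessage(err), "couplet 6")
  expect_error(identify_specimen(list(nonsense_trait = 1)),
               class = "key_structure_error")
})

test_that("identification is deterministic and ambiguity shrinks with data", {
  obs <- list(flanges_serrated = FALSE, collar_fused = FALSE)
  a <- identify_specimen(obs)
  b <- identify_specimen(obs)
  expect_identical(a$taxa, b$taxa)
  # adding observations never enlarges the candidate set
  additions <- list(
    list(radiolar_eyes = FALSE),
    list(radiolar_eyes = FALSE, band_count = 0),
    list(radiolar_eyes = FALSE, band_count = 0, thoracic_chaetigers = 8,
         tooth_rows = 6))
  prev <- a$taxa
  for (extra in additions) {
    cur <- identify_specimen(c(obs, extra))$taxa
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("every species has a trait profile reaching its terminal", {
  profiles <- list(
    "Pseudobranchiomma grandis" = list(flanges_serrated = TRUE,
      serrations_along_most = TRUE, radiolar_eyes = TRUE),
    "Pseudobranchiomma orientalis" = list(flanges_serrated = TRUE,
      serrations_along_most = TRUE, radiolar_eyes = FALSE,
      serration_pairs = 25, tooth_rows = 7),
    "Pseudobranchiomma paulista" = list(flanges_serrated = TRUE,
      serrations_along_most = TRUE, radiolar_eyes = FALSE,
      serration_pairs = 16, tooth_rows = 4),
    "Pseudobranchiomma pallida" = list(flanges_serrated = TRUE,
      serrations_along_most = TRUE, radiolar_eyes = FALSE,
      serration_pairs = 6, dark_bands = FALSE, tooth_rows = 3),
    "Pseudobranchiomma emersoni" = list(flanges_serrated = TRUE,
      serrations_along_most = FALSE, serration_pairs = 10, tooth_rows = 5),
    "Pseudobranchiomma paraemersoni" = list(flanges_serrated = TRUE,
      serrations_along_most = FALSE, serration_pairs = 4,
      thoracic_chaetigers = 5),
    "Pseudobranchiomma schizogenica" = list(flanges_serrated = TRUE,
      serrations_along_most = FALSE, serration_pairs = 7, tooth_rows = 4),
    "Pseudobranchiomma punctata" = list(flanges_serrated = FALSE,
      collar_fused = TRUE),
    "Pseudobranchiomma tricolor" = list(flanges_serrated = FALSE,
      collar_fused = FALSE, radiolar_eyes = FALSE, band_count = 12),
    "Pseudobranchiomma zebuensis" = list(flanges_serrated = FALSE,
      collar_fused = FALSE, radiolar_eyes = FALSE, band_count = 0,
      thoracic_chaetigers = 8, tooth_rows = 6),
    "Pseudobranchiomma longa" = list(flanges_serrated = FALSE,
      collar_fused = FALSE, radiolar_eyes = FALSE, band_count = 2,
      thorax_broader_than_long = TRUE, thoracic_chaetigers = 7,
      crown_spiral = TRUE),
    "Pseudobranchiomma perkinsi" = list(flanges_serrated = FALSE,
      collar_fused = FALSE, radiolar_eyes = FALSE, band_count = 0,
      thorax_broader_than_long = FALSE, thoracic_chaetigers = 12,
      crown_spiral = FALSE),
    "Pseudobranchiomma minima" = list(flanges_serrated = FALSE,
      collar_fused = FALSE, radiolar_eyes = FALSE, band_count = 0,
      thorax_broader_than_long = FALSE, thoracic_chaetigers = 5,
      first_chaetiger_elongate = FALSE),
    "Pseudobranchiomma tarantoensis" = list(flanges_serrated = FALSE,
      collar_fused = FALSE, radiolar_eyes = FALSE, band_count = 0,
      thorax_broader_than_long = FALSE, thoracic_chaetigers = 8,
      first_chaetiger_elongate = TRUE))
  for (sp in names(profiles)) {
    res <- identify_specimen(profiles[[sp]])
    expect_true(sp %in% res$taxa, label = sp)
  }
})
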