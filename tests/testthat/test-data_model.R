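test_that("clustered_dataset validates structure and preserves cluster order", {
  d <- toy_dataset()
  expect_s3_class(d, "clustered_dataset")
  expect_equal(length(d$clusters), 3)
  expect_equal(d$N, 30)
  expect_equal(d$clusters, c("a", "b", "c"))
  expect_equal(unname(d$n_k), rep(10L, 3))

  df <- toy_frame()
  df$dvt[1] <- 2
  expect_error(clustered_dataset(df, "study", "dvt"), class = "siecv_validation_error")

  df <- toy_frame()
  df$study <- "a"
  expect_error(clustered_dataset(df, "study", "dvt"), class = "siecv_validation_error")

  df <- toy_frame()
  df$age[5] <- NA
  expect_error(clustered_dataset(df, "study", "dvt"),
               regexp = "age", class = "siecv_validation_error")

  expect_error(clustered_dataset(toy_frame(), "centre", "dvt"),
               class = "siecv_config_error")
})

test_that("file round-trip preserves values and cluster order", {
  d <- toy_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)
  d2 <- load_dataset(path, "study", "dvt")
  expect_equal(d2$data, d$data, ignore_attr = TRUE)
  expect_identical(d2$clusters, d$clusters)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(d, tsv, sep = "\t")
  expect_equal(load_dataset(tsv, "study", "dvt", sep = "\t")$N, d$N)

  expect_error(load_dataset("no/such/file.csv", "study", "dvt"),
               class = "siecv_config_error")
})

test_that("build_design computes transforms, centering and interactions", {
  df <- data.frame(
    study = rep(c("a", "b"), each = 4),
    y = rep(c(0, 1), 4),
    age = c(50, 75, 25, 50, 40, 60, 80, 100),
    sex = c(1, 1, 0, 0, 1, 0, 1, 0),
    ddimer = c(1, 0, 1, 0, 0, 1, 1, 0),
    dur = c(1, 2, 4, 8, 1, 1, 2, 4)
  )
  d <- clustered_dataset(df, "study", "y")
  spec <- list(
    term_scale("age25", "age", 25),
    term_square_centered("age25_sq", "age25"),
    term_interaction("sex_x_ddimer", c("sex", "ddimer")),
    term_log("log_dur", "dur")
  )
  X <- build_design(d, spec)
  expect_identical(colnames(X),
                   c("(Intercept)", "age25", "age25_sq", "sex_x_ddimer", "log_dur"))
  expect_equal(unname(X[1, "age25"]), 2.0)
  # cluster a mean age = 50: ((75-50)/25)^2 = 1
  expect_equal(unname(X[2, "age25_sq"]), 1.0)
  expect_equal(unname(X[, "sex_x_ddimer"]), df$sex * df$ddimer)
  expect_equal(unname(X[, "log_dur"]), log(df$dur))

  # purity: identical inputs give identical output
  expect_identical(X, build_design(d, spec))

  dfneg <- df
  dfneg$dur[1] <- 0
  expect_error(
    build_design(clustered_dataset(dfneg, "study", "y"), list(term_log("ld", "dur"))),
    class = "siecv_validation_error"
  )
})

test_that("dropping a cluster commutes with design building except for row-level centering", {
  df <- toy_frame()
  d <- clustered_dataset(df, "study", "dvt")
  spec <- list(term_main("sex"), term_square_centered("age_sq", "age"))
  X_full <- build_design(d, spec)

  # whole-cluster drop: per-cluster centering of the remaining clusters is
  # unchanged, so the two orders agree for every term
  d_ab <- subset_clusters(d, c("a", "b"))
  X_sub <- build_design(d_ab, spec)
  expect_equal(unname(X_sub), unname(X_full[cluster_rows <- df$study %in% c("a", "b"), ]))

  # dropping rows *within* a cluster changes that cluster's mean: the
  # centered term is recomputed on the reduced data, plain terms are not
  keep <- rep(TRUE, nrow(df)); keep[c(2, 4)] <- FALSE
  d_red <- clustered_dataset(df[keep, ], "study", "dvt")
  X_red <- build_design(d_red, spec)
  expect_equal(X_red[, "sex"], X_full[keep, "sex"])
  expect_false(isTRUE(all.equal(X_red[, "age_sq"], X_full[keep, "age_sq"])))
})

test_that("model_spec enforces disjointness, uniqueness and forced-subset rules", {
  t1 <- term_main("a"); t2 <- term_main("b")
  s <- model_spec(included = list(t1), candidates = list(t2), forced = "a")
  expect_s3_class(s, "model_spec")
  expect_error(model_spec(included = list(t1), candidates = list(t1)),
               class = "siecv_validation_error")
  expect_error(model_spec(included = list(t1), forced = "zzz"),
               class = "siecv_validation_error")
  expect_error(term_interaction("ab", "a"), class = "siecv_validation_error")
})

test_that("model specifications survive the config-list round trip", {
  s <- model_spec(
    included = list(term_main("malignancy"), term_scale("age25", "age", 25)),
    candidates = list(term_square_centered("age25_sq", "age25"),
                      term_interaction("mal_x_age", c("malignancy", "age25"))),
    forced = "malignancy"
  )
  s2 <- spec_from_list(spec_to_list(s))
  expect_equal(siecv:::term_names(s2$included), siecv:::term_names(s$included))
  expect_equal(siecv:::term_names(s2$candidates), siecv:::term_names(s$candidates))
  expect_equal(s2$forced, s$forced)
  expect_equal(s2$included[[2]]$by, 25)
  # YAML round trip of the same structure
  y <- yaml::as.yaml(spec_to_list(s))
  s3 <- spec_from_list(yaml::yaml.load(y))
  expect_equal(siecv:::term_names(s3$candidates), siecv:::term_names(s$candidates))
})
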