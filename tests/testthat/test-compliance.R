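reg <- mrl_registry()
analytes <- reg$per_analyte$analyte
ccas <- stats::setNames(c(70, rep(115, 7)), analytes)      # TMP first in list
ccas[["Sulfamethazine"]] <- 114.0
loqs <- stats::setNames(rep(5, 8), analytes)
all_confirmed <- stats::setNames(as.list(rep(TRUE, 8)), analytes)

test_that("the default registry encodes the regulatory limits", {
  expect_equal(reg$group_mrl_sulfonamides, 100)
  pa <- reg$per_analyte
  expect_equal(pa$mrl[pa$analyte == "Trimethoprim"], 50)
  expect_false(pa$sulfonamide[pa$analyte == "Trimethoprim"])
  expect_true(all(pa$sulfonamide[pa$analyte != "Trimethoprim"]))
  expect_true(all(pa$mrl[pa$analyte != "Trimethoprim"] == 100))
})

test_that("an all-zero sample is not detected and the group conforms", {
  concs <- stats::setNames(rep(0, 8), analytes)
  dec <- screen_sample(concs, list(), reg, ccas, loqs)
  expect_true(all(dec$per_analyte$status == "not_detected"))
  expect_identical(dec$group_status, "conforming")
  expect_equal(dec$sum_sulfonamides, 0)
})

test_that("a confirmed incurred concentration above CCalpha is nonconforming", {
  concs <- stats::setNames(rep(0, 8), analytes)
  concs[["Sulfamethazine"]] <- 1062.9
  dec <- screen_sample(concs, all_confirmed, reg, ccas, loqs)
  pa <- dec$per_analyte
  expect_identical(pa$status[pa$analyte == "Sulfamethazine"], "nonconforming")
  expect_identical(dec$group_status, "nonconforming")
  expect_true(any(grepl("CCalpha", dec$rationale)))
})

test_that("the summed-sulfonamide rule fires below individual CCalphas", {
  concs <- stats::setNames(rep(0, 8), analytes)
  concs[["Sulfapyridine"]] <- 60
  concs[["Sulfamerazine"]] <- 60
  dec <- screen_sample(concs, all_confirmed, reg, ccas, loqs)
  pa <- dec$per_analyte
  expect_identical(pa$status[pa$analyte == "Sulfapyridine"], "conforming")
  expect_identical(pa$status[pa$analyte == "Sulfamerazine"], "conforming")
  expect_equal(dec$sum_sulfonamides, 120)
  expect_identical(dec$group_status, "nonconforming")
})

test_that("unconfirmed identity never yields nonconforming", {
  concs <- stats::setNames(rep(0, 8), analytes)
  concs[["Sulfamethazine"]] <- 1062.9
  dec <- screen_sample(concs, list(), reg, ccas, loqs)
  pa <- dec$per_analyte
  expect_identical(pa$status[pa$analyte == "Sulfamethazine"], "conforming")
  expect_true(any(grepl("not confirmed", dec$rationale)))
  # unconfirmed concentrations are excluded from the group sum
  expect_equal(dec$sum_sulfonamides, 0)
  expect_identical(dec$group_status, "conforming")
})

test_that("missing decision limits are reported", {
  concs <- c(Sulfamethazine = 10)
  expect_error(screen_sample(concs, list(), reg, ccas[-match("Sulfamethazine",
                                                             names(ccas))],
                             loqs), "missing CCalpha")
  expect_error(screen_sample(concs, list(), reg, ccas, loqs[0]),
               "missing LOQ")
})

test_that("raising a concentration never rescues a nonconforming sample", {
  withr::local_seed(31)
  rank_status <- function(s)
    match(s, c("not_detected", "below_loq", "conforming", "nonconforming"))
  for (i in 1:40) {
    concs <- stats::setNames(runif(8, 0, 200), analytes)
    dec1 <- screen_sample(concs, all_confirmed, reg, ccas, loqs)
    j <- sample(8, 1)
    concs2 <- concs
    concs2[[j]] <- concs2[[j]] + runif(1, 0, 500)
    dec2 <- screen_sample(concs2, all_confirmed, reg, ccas, loqs)
    expect_gte(rank_status(dec2$per_analyte$status[j]),
               rank_status(dec1$per_analyte$status[j]))
    if (dec1$group_status == "nonconforming")
      expect_identical(dec2$group_status, "nonconforming")
  }
})

test_that("group status depends only on the sulfonamide sum", {
  withr::local_seed(32)
  sulfas <- analytes[reg$per_analyte$sulfonamide]
  for (total in c(80, 120, 300)) {
    statuses <- vapply(1:10, function(i) {
      w <- rexp(length(sulfas)); w <- w / sum(w) * total
      # redraw until each share is quantifiable but below its own CCalpha
      w <- pmin(pmax(w, loqs[sulfas] + 0.1), ccas[sulfas] - 0.1)
      w <- w / sum(w) * total
      if (any(w >= ccas[sulfas] | w < loqs[sulfas])) return(NA_character_)
      concs <- stats::setNames(rep(0, 8), analytes)
      concs[sulfas] <- w
      screen_sample(concs, all_confirmed, reg, ccas, loqs)$group_status
    }, character(1))
    statuses <- statuses[!is.na(statuses)]
    expect_true(length(unique(statuses)) <= 1)
    if (length(statuses))
      expect_identical(unique(statuses),
                       if (total >= 100) "nonconforming" else "conforming")
  }
})

test_that("concentrations between LOQ and CCalpha are never nonconforming", {
  withr::local_seed(33)
  for (i in 1:30) {
    a <- sample(analytes, 1)
    concs <- stats::setNames(rep(0, 8), analytes)
    concs[[a]] <- runif(1, loqs[[a]], ccas[[a]] - 1e-9)
    dec <- screen_sample(concs, all_confirmed, reg, ccas, loqs)
    expect_false(any(dec$per_analyte$status == "nonconforming"))
  }
})

test_that("loq_policy_check applies class ceilings inclusively", {
  res <- loq_policy_check(c(Sulfamethazine = 5, Trimethoprim = 25))
  expect_true(res$pass[res$analyte == "Sulfamethazine"])
  expect_false(res$pass[res$analyte == "Trimethoprim"])
  at_limit <- loq_policy_check(c(Trimethoprim = 20))
  expect_true(at_limit$pass)
  expect_error(loq_policy_check(c(X = 5), policy = c(sulfonamide = 10),
                                classes = c(X = "quinolone")),
               "no policy limit")
})
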