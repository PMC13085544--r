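# Samples with exact summary statistics, for cross-checking the
# summary-based tests against stats::t.test on real vectors.
exact_sample <- function(mean, sd, n) {
  z <- scale(rnorm(n))  # mean 0, sd 1 (n - 1 denominator)
  as.numeric(mean + sd * z)
}

test_that("summary-based t-tests agree with t.test on matching samples", {
  set.seed(1)
  cases <- list(c(911.61, 52.59, 4, 775.89, 56.11, 5),
                c(686.44, 42.98, 6, 519.19, 30.59, 6),
                c(10, 2, 8, 11, 5, 12))
  for (cs in cases) {
    a <- exact_sample(cs[1], cs[2], cs[3])
    b <- exact_sample(cs[4], cs[5], cs[6])
    ga <- group_summary(cs[1], cs[2], cs[3])
    gb <- group_summary(cs[4], cs[5], cs[6])
    for (tt in c("student", "welch")) {
      cmp <- compare_groups(ga, gb, test = tt)
      ref <- t.test(b, a, var.equal = (tt == "student"))
      expect_equal(cmp$t, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(cmp$df, unname(ref$parameter), tolerance = 1e-9)
      expect_equal(cmp$p, ref$p.value, tolerance = 1e-9)
      expect_equal(cmp$ci, as.numeric(ref$conf.int), tolerance = 1e-7)
    }
  }
})

test_that("identical groups compare as no difference", {
  g <- group_summary(5, 1, 6)
  cmp <- compare_groups(g, g, test = "student")
  expect_equal(cmp$diff, 0)
  expect_equal(cmp$p, 1)
  expect_equal(cmp$hedges_g, 0)
})

test_that("Student and Welch coincide for equal n and equal SD", {
  a <- group_summary(10, 3, 7); b <- group_summary(12, 3, 7)
  s <- compare_groups(a, b, test = "student")
  w <- compare_groups(a, b, test = "welch")
  expect_equal(s$t, w$t, tolerance = 1e-12)
  expect_equal(s$df, w$df, tolerance = 1e-12)
  expect_equal(s$p, w$p, tolerance = 1e-12)
})

test_that("auto selection switches to Welch only for unequal variances", {
  expect_equal(compare_groups(group_summary(0, 1, 10),
                              group_summary(1, 1.2, 10), "auto")$test,
               "student")
  expect_equal(compare_groups(group_summary(0, 1, 10),
                              group_summary(1, 6, 10), "auto")$test,
               "welch")
})

test_that("published effect sizes are reproduced from the printed summaries", {
  tab <- table1_summaries()
  g_of <- function(endpoint, species) {
    sub <- tab[tab$endpoint == endpoint & tab$species == species, ]
    hedges_g(as.list(sub[sub$treatment == "Cryo", c("mean", "sd", "n")]),
             as.list(sub[sub$treatment == "Laser", c("mean", "sd", "n")]))
  }
  expect_equal(g_of("lesion_diameter_um", "mouse"), -2.21, tolerance = 0.005)
  expect_equal(g_of("lesion_diameter_um", "rat"), -4.14, tolerance = 0.005)
  expect_equal(g_of("lesion_diameter_um", "rabbit"), -2.82, tolerance = 0.005)
  expect_equal(g_of("thickness_ratio", "rabbit"), 4.80, tolerance = 0.005)
  # antisymmetry
  a <- group_summary(911.61, 52.59, 4); b <- group_summary(775.89, 56.11, 5)
  expect_equal(hedges_g(a, b), -hedges_g(b, a))
  # the exact gamma correction is close to, but distinct from, the default
  expect_equal(hedges_g(a, b, exact = TRUE), hedges_g(a, b), tolerance = 0.01)
  expect_false(hedges_g(a, b, exact = TRUE) == hedges_g(a, b))
})

test_that("Holm-Sidak follows its step-down formula and trivial cases", {
  expect_equal(holm_sidak(0.2), 0.2)
  expect_equal(holm_sidak(c(1, 1, 1)), c(1, 1, 1))
  p <- c(0.01, 0.04, 0.03)
  # direct enumeration of the formula
  o <- order(p)       # 1, 3, 2
  m <- 3
  step1 <- 1 - (1 - 0.01)^3
  step2 <- max(step1, 1 - (1 - 0.03)^2)
  step3 <- max(step2, 1 - (1 - 0.04)^1)
  expect_equal(holm_sidak(p), c(step1, step3, step2), tolerance = 1e-14)
  # monotone in the sorted order and never below the raw p
  set.seed(2)
  for (k in 1:20) {
    pv <- runif(6)
    adj <- holm_sidak(pv)
    expect_true(all(adj >= pv - 1e-15))
    expect_true(all(diff(adj[order(pv)]) >= -1e-15))
    expect_true(all(adj <= 1))
  }
  expect_error(holm_sidak(c(0.5, 0)), NULL)
})

test_that("balanced two-way ANOVA matches the closed-form decomposition", {
  set.seed(31)
  species <- rep(c("mouse", "rat", "rabbit"), each = 8)
  treatment <- rep(rep(c("Cryo", "Laser"), each = 4), times = 3)
  value <- rnorm(24, 100, 10) +
    ifelse(treatment == "Laser", -20, 0) +
    ifelse(species == "rat", 15, ifelse(species == "rabbit", -10, 0))
  tab <- data.frame(species, treatment, value)
  got <- two_way_anova(tab)
  # closed-form balanced decomposition
  mu <- mean(value)
  mu_a <- tapply(value, species, mean)
  mu_b <- tapply(value, treatment, mean)
  mu_ab <- tapply(value, interaction(species, treatment), mean)
  ss_a <- 8 * sum((mu_a - mu)^2)
  ss_b <- 12 * sum((mu_b - mu)^2)
  ss_ab <- 4 * sum(vapply(names(mu_ab), function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    (mu_ab[k] - mu_a[parts[1]] - mu_b[parts[2]] + mu)^2
  }, 0))
  ss_e <- sum((value - ave(value, species, treatment))^2)
  ms_e <- ss_e / 18
  f_ref <- c(ss_a / 2, ss_b / 1, ss_ab / 2) / ms_e
  expect_equal(got$anova$F, unname(f_ref), tolerance = 1e-9)
  expect_equal(got$residual_df, 18)
  expect_equal(got$anova$p,
               unname(pf(f_ref, c(2, 1, 2), 18, lower.tail = FALSE)),
               tolerance = 1e-9)
  expect_true(all(got$posthoc$p_adj >= got$posthoc$p - 1e-15))
})

test_that("empty or undersized cells are refused by name", {
  tab <- data.frame(species = c("mouse", "mouse", "rat", "rat"),
                    treatment = c("Cryo", "Cryo", "Cryo", "Laser"),
                    value = rnorm(4))
  expect_error(two_way_anova(tab), "mouse:Laser")
})

test_that("null data give uniform-ish p and adjusted >= raw over seeds", {
  set.seed(77)
  sig <- 0
  for (k in 1:30) {
    tab <- data.frame(
      species = rep(c("mouse", "rat", "rabbit"), each = 6),
      treatment = rep(rep(c("Cryo", "Laser"), each = 3), 3),
      value = rnorm(18, 100, 5))
    got <- two_way_anova(tab)
    expect_true(all(got$posthoc$p_adj >= got$posthoc$p - 1e-15))
    sig <- sig + (got$anova$p[2] < 0.05)
  }
  expect_lte(sig, 6)  # ~5% nominal false positive rate
})

test_that("cohorts at the published effect sizes are reliably significant", {
  # Simulated power at the printed means/SDs/group sizes: the mouse and rat
  # contrasts are detected almost always; the rabbit contrast (n = 3 + 3,
  # Holm-Sidak adjusted) has simulated power near 0.84, which bounds the
  # all-three-significant rate.
  tab1 <- table1_summaries()
  lesion <- tab1[tab1$endpoint == "lesion_diameter_um", ]
  hits <- 0; per <- c(mouse = 0, rat = 0, rabbit = 0)
  for (k in 1:200) {
    coh <- generate_cohort(lesion, seed = 5000 + k)
    got <- two_way_anova(coh)
    sig <- got$posthoc$p_adj < 0.05
    names(sig) <- got$posthoc$species
    per <- per + sig[names(per)]
    hits <- hits + all(sig)
  }
  expect_gte(per[["rat"]] / 200, 0.95)
  expect_gte(per[["mouse"]] / 200, 0.90)
  expect_gte(hits / 200, 0.75)
})

test_that("the summary table replica reports the printed diff and g columns", {
  out <- reproduce_table1()
  row <- function(e, s) out[out$endpoint == e & out$species == s, ]
  expect_equal(row("lesion_diameter_um", "mouse")$diff, -135.7, tolerance = 1e-3)
  expect_equal(row("lesion_diameter_um", "rat")$hedges_g, -4.14, tolerance = 0.005)
  expect_equal(row("thickness_ratio", "rabbit")$diff, 0.06, tolerance = 1e-9)
  expect_true(all(c("sem", "ci_lo", "ci_hi", "p", "t", "df") %in% names(out)))
  expect_equal(nrow(out), 6)
})
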