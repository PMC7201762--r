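test_that("bicor anchors: self, sign flip, affine equivariance", {
  set.seed(41)
  x <- rnorm(30)
  expect_equal(bicor(x, x), 1)
  expect_equal(bicor(x, -x), -1)
  y <- rnorm(30)
  expect_equal(bicor(x, y), bicor(x, 3 * y + 5), tolerance = 1e-12)
  expect_equal(bicor(x, y), -bicor(x, -2 * y + 1), tolerance = 1e-12)
})

test_that("bicor matches the definitional oracle on hand-sized vectors", {
  set.seed(43)
  for (rep in 1:25) {
    x <- rnorm(7); y <- rnorm(7)
    expect_equal(bicor(x, y), bicor_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("zero-MAD input falls back to Pearson or errors, as configured", {
  x <- c(rep(1, 8), 2)  # MAD 0, not constant
  y <- rnorm(9)
  expect_warning(r <- bicor(x, y), "zero MAD")
  expect_equal(r, cor(x, y))
  expect_error(bicor(x, y, zero_mad = "error"), "zero MAD")
  expect_error(bicor(1:3, 1:3), "at least 4")
})

test_that("bicor shrugs off a gross outlier that wrecks Pearson", {
  set.seed(45)
  wins <- replicate(100, {
    n <- 200
    x <- rnorm(n)
    y <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(n)
    x[1] <- 30; y[1] <- -30
    abs(bicor(x, y) - 0.8) < abs(cor(x, y) - 0.8)
  })
  expect_gte(mean(wins), 0.9)
})

test_that("spearman anchors and midrank tie handling", {
  x <- sort(rnorm(20))
  expect_equal(spearman_rho(x, exp(x)), 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 1, 2)), -0.5)
  set.seed(47)
  for (rep in 1:10) {
    x <- sample(1:3, 5, replace = TRUE) + 0  # ties on purpose
    y <- rnorm(5)
    if (sd(x) == 0) next
    # oracle: Pearson product-moment formula applied to midranks
    rx <- rank(x); ry <- rank(y)
    o <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(spearman_rho(x, y), o, tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), rnorm(5)), "constant")
})

test_that("both correlation methods recover a clean generating rho", {
  set.seed(49)
  n <- 100; rho <- 0.6
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  expect_lt(abs(bicor(x, y) - rho), 0.15)
  expect_lt(abs(spearman_rho(x, y) - rho), 0.15)
})

test_that("within-group correlation tables expose planted coupling", {
  cfg <- simulation_config(n_current = 50, n_never = 50, n_probes = 300,
                           n_genes = 150, n_signature = 20, n_dcs_pairs = 8,
                           rng_seed = 13)
  st <- generate_study(cfg)
  ct <- correlate_probes_genes(st$methylation[st$truth_signature_probes, ],
                               st$expression, st$metadata, method = "bicor")
  expect_s3_class(ct, "correlation_table")
  expect_true(all(abs(ct$r_current) <= 1, na.rm = TRUE))
  key <- paste(ct$probe_id, ct$gene_id)
  tk <- paste(st$truth_dcs_pairs$probe_id, st$truth_dcs_pairs$gene_id)
  planted <- ct[key %in% tk, ]
  hi <- pmax(abs(planted$r_current), abs(planted$r_never))
  lo <- pmin(abs(planted$r_current), abs(planted$r_never))
  expect_gte(mean(hi >= 0.6), 0.85)
  expect_gte(mean(lo <= 0.3), 0.85)
})

test_that("constant genes inside a group are flagged, small groups rejected", {
  st <- generate_study(tiny_config())
  ex <- st$expression
  ex[1, ] <- 7
  ws <- capture_warnings(
    ct <- correlate_probes_genes(st$methylation[1:5, ], ex, st$metadata,
                                 method = "spearman"))
  expect_match(ws, "constant", all = FALSE)
  expect_true(all(is.na(ct$r_current[ct$gene_id == rownames(ex)[1]])))
  md <- st$metadata
  md$smoking_status[md$smoking_status == "never"] <- "current"
  md$smoking_status[1:3] <- "never"
  expect_error(correlate_probes_genes(st$methylation[1:5, ], st$expression,
                                      md, "spearman"), "fewer than 4")
})

test_that("the two-threshold rule selects exactly the crossing pairs", {
  tab <- data.frame(probe_id = paste0("p", 1:4), gene_id = paste0("g", 1:4),
                    method = "bicor",
                    r_current = c(0.8, 0.5, 0.6, -0.1),
                    r_never = c(0.1, 0.5, 0.3, -0.7))
  d <- dcs_select(tab, ts1 = 0.3, ts2 = 0.6)
  # high/low selected; mid/mid not; boundary 0.6/0.3 inclusive; sign ignored
  expect_setequal(d$pairs$probe_id, c("p1", "p3", "p4"))
  expect_setequal(d$genes, c("g1", "g3", "g4"))
  expect_error(dcs_select(tab, ts1 = 0.7, ts2 = 0.6), "ts1 < ts2")
})

test_that("DCS selection is monotone in TS2 and anti-monotone in TS1", {
  set.seed(51)
  tab <- data.frame(probe_id = rep(paste0("p", 1:40), each = 10),
                    gene_id = rep(paste0("g", 1:10), times = 40),
                    method = "bicor",
                    r_current = runif(400, -1, 1),
                    r_never = runif(400, -1, 1))
  key <- function(d) paste(d$pairs$probe_id, d$pairs$gene_id)
  base <- dcs_select(tab, 0.3, 0.6)
  expect_true(all(key(dcs_select(tab, 0.3, 0.8)) %in% key(base)))
  expect_true(all(key(dcs_select(tab, 0.2, 0.6)) %in% key(base)))
})

test_that("weight network connectivity matches forced configurations", {
  # m identical genes: all |cor| = 1, k_i = m - 1
  f <- rnorm(30)
  ex <- matrix(rep(f, 5), 5, 30, byrow = TRUE,
               dimnames = list(paste0("g", 1:5), NULL))
  ex <- ex * c(1, 2, 3, -1, -2) + c(0, 1, 2, 3, 4)
  net <- build_weight_network(ex, beta_soft = 6)
  expect_equal(unname(net$connectivity), rep(4, 5), tolerance = 1e-10)

  # soft power blowing up sends all sub-unit adjacencies to zero
  set.seed(53)
  ex2 <- matrix(rnorm(8 * 40), 8, 40, dimnames = list(paste0("r", 1:8), NULL))
  net2 <- build_weight_network(ex2, beta_soft = 200)
  expect_lt(max(net2$connectivity), 1e-6)
  expect_error(build_weight_network(ex2[1:2, ]), "at least 3")
  ex2[1, ] <- 5
  expect_warning(build_weight_network(ex2), "constant")
})

test_that("hub calling flags exactly the constructed high-connectivity genes", {
  # 9 hub genes carry a shared factor exactly; 25 periphery genes load on it
  # with c = 0.75, giving hub connectivity 8 + 25 * 0.75^6 ~ 12.4 (> 10.75)
  # and periphery connectivity ~ 2.4 (< 10.75), all by exact construction.
  n <- 40
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 26), n))))[, -1]  # centered o.n.
  f <- Q[, 1]; E <- Q[, 2:26]
  cc <- 0.75
  hubs <- t(matrix(f, n, 9))
  periph <- t(cc * f + sqrt(1 - cc^2) * E)
  ex <- rbind(hubs, periph)
  rownames(ex) <- c(sprintf("hub%02d", 1:9), sprintf("per%02d", 1:25))
  net <- build_weight_network(ex, beta_soft = 6, hub_threshold = 10.75)
  expect_setequal(net$hubs, sprintf("hub%02d", 1:9))
  k_hub <- 8 + 25 * cc^6
  expect_equal(unname(net$connectivity["hub01"]), k_hub, tolerance = 1e-8)
})

test_that("gene-set intersection is exact and order-stable", {
  s <- intersect_sets(c("C", "A", "B"), c("B", "D", "C"))
  expect_equal(s$common_genes, c("B", "C"))
  expect_equal(intersect_sets(c("A"), c("B"))$common_genes, character(0))
})
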