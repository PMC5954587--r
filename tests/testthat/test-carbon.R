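make_tree <- function(leaves = 300, shoots = c(30, 30, 30), branches = 600,
                      coarse = 300, fine = matrix(c(40, 30, 20, 5, 4, 3), 2, 3,
                                                  byrow = TRUE),
                      fruits = 0, reserves = 80) {
  tree_carbon_state(leaves, shoots, branches, coarse, fine, fruits, reserves)
}

test_that("maintenance respiration is the organ x step double sum", {
  gw <- default_growth_params()
  zero <- tree_carbon_state(0, c(0, 0, 0), 0, 0, matrix(0, 2, 2))
  expect_equal(maintenance_respiration(zero, rep(20, 24), rep(1, 24)), 0)

  tree <- make_tree()
  temps <- runif(24, 5, 35)
  r <- maintenance_respiration(tree, temps, rep(1, 24), gw)
  # independent double-sum oracle
  organs <- c(gw$km_leaf * 300, gw$km_shoot * 90, gw$km_branch * 600,
              gw$km_coarse * 300, gw$km_fine * sum(tree$fine_roots),
              gw$km_fruit * 0)
  oracle <- sum(vapply(temps, function(t)
    sum(organs) * gw$q10_resp^((t - 20) / 10), numeric(1))) / 24
  expect_equal(r, oracle, tolerance = 1e-12)
  # Q10 law: +10 degC multiplies by Q10
  r10 <- maintenance_respiration(tree, temps + 10, rep(1, 24), gw)
  expect_equal(r10 / r, gw$q10_resp, tolerance = 1e-12)
})

test_that("the assimilate pool draws reserves for respiration deficits", {
  tree <- make_tree(reserves = 10)
  ap <- daily_assimilate_pool(2, tree, resp_m = 5, fruit_active = FALSE)
  expect_equal(ap$pool, 0)
  expect_equal(ap$reserve_draw, 3)
  expect_equal(ap$state$reserves, 7)
  expect_false(ap$starved)
  # reserves exhausted: pool floored at zero, starvation flagged
  ap2 <- daily_assimilate_pool(0, make_tree(reserves = 1), resp_m = 5)
  expect_equal(ap2$pool, 0)
  expect_equal(ap2$state$reserves, 0)
  expect_true(ap2$starved)
  expect_equal(ap2$unpaid, 4)
  # remobilization min() oracle
  expect_equal(remobilize_reserves(100, demand = 12, supply = 4, cap = 0.05),
               min(0.05 * 100, 8))
  expect_equal(remobilize_reserves(100, demand = 4.5, supply = 4, cap = 0.05),
               0.5)
})

test_that("fruit number recurrence drives alternation and heat damage", {
  gw <- default_growth_params()
  # recurrence oracle
  expect_equal(determine_fruit_number(500, 1000, 0, gw),
               max(0, gw$fn_a * 1000 - gw$fn_b * 500))
  # OFF year (no fruits) with many nodes gives the maximal ON crop
  expect_equal(determine_fruit_number(0, 1000, 0, gw), gw$fn_a * 1000)
  # total heat kill
  gw2 <- gw; gw2$heat_reduction <- 1
  expect_equal(determine_fruit_number(100, 1000, heat_days = 3, gw2), 0)
  # each hot day trims multiplicatively
  expect_equal(determine_fruit_number(0, 1000, heat_days = 2, gw),
               gw$fn_a * 1000 * (1 - gw$heat_reduction)^2)
})

test_that("allocation conserves substrate and respects fruit priority", {
  gw <- default_growth_params()
  tree <- make_tree()
  a0 <- allocate_growth(0, tree, 500, 10, TRUE, TRUE, gw)
  expect_true(all(a0$growth == 0))

  # sink-limited fruits receive exactly their demand
  al <- allocate_growth(100, tree, fn = 50, dtt = 10, TRUE, TRUE, gw)
  demand_dm <- 50 * gw$fruit_pot_rate * 10
  expect_equal(al$growth[["fruit"]], demand_dm, tolerance = 1e-12)
  expect_true(al$fruit_sink_limited)

  # source-limited: fruits capped at p_fruit_max of the pool
  al2 <- allocate_growth(1, tree, fn = 5000, dtt = 15, TRUE, TRUE, gw)
  expect_equal(al2$growth[["fruit"]], gw$p_fruit_max * 1 * gw$pv_fruit,
               tolerance = 1e-12)
  expect_false(al2$fruit_sink_limited)

  # substrate conservation over random cases
  pv <- c(leaf = gw$pv_leaf, shoot = gw$pv_shoot, branch = gw$pv_branch,
          coarse = gw$pv_coarse, fine = gw$pv_fine, fruit = gw$pv_fruit)
  set.seed(3)
  for (k in 1:30) {
    pool <- runif(1, 0, 20)
    fn <- runif(1, 0, 2000)
    dtt <- runif(1, 0, 15)
    ga <- runif(1) < 0.8
    fa <- runif(1) < 0.6
    al <- allocate_growth(pool, tree, fn, dtt, ga, fa, gw)
    spent <- sum(al$growth / pv[names(al$growth)])
    expect_lt(abs(spent + al$to_reserves - pool), 1e-9)
    expect_gte(al$resp_g, 0)
    if (!ga) expect_true(all(al$growth[c("leaf", "shoot", "branch",
                                         "coarse", "fine")] == 0))
  }
  bad <- gw; bad$part_leaf <- 0.9
  expect_error(allocate_growth(1, tree, 0, 0, TRUE, FALSE, bad),
               "partitioning sum")
})

test_that("senescence is first-order and conserves litter", {
  gw <- default_growth_params()
  tree <- make_tree()
  none <- gw; none$leaf_turnover <- 0; none$fine_turnover <- 0
  s0 <- senescence_turnover(tree, none)
  expect_equal(s0$state$leaves, tree$leaves)
  expect_equal(sum(s0$litter), 0)

  s1 <- senescence_turnover(tree, gw)
  expect_equal(s1$litter[["leaf"]],
               tree$leaves - s1$state$leaves, tolerance = 1e-12)
  expect_equal(s1$litter[["fine"]],
               sum(tree$fine_roots) - sum(s1$state$fine_roots),
               tolerance = 1e-12)
  # k days of decay with no growth: B0 (1 - lambda)^k
  st <- tree
  for (d in 1:30) st <- senescence_turnover(st, gw)$state
  expect_equal(st$leaves, tree$leaves * (1 - gw$leaf_turnover)^30,
               tolerance = 1e-9)
})

test_that("shoot cohorts age into branches with conservation", {
  tree <- make_tree(shoots = c(10, 20, 30), branches = 100)
  woody0 <- sum(tree$shoots) + tree$branches
  t1 <- shoots_to_branches(tree)
  expect_equal(t1$branches, 130)
  expect_equal(t1$shoots, c(0, 10, 20))
  expect_equal(sum(t1$shoots) + t1$branches, woody0)
  # three boundaries against a hand-rolled queue
  queue <- c(10, 20, 30); branches <- 100
  st <- tree
  for (y in 1:3) {
    branches <- branches + queue[3]
    queue <- c(0, queue[1], queue[2])
    st <- shoots_to_branches(st)
  }
  expect_equal(st$shoots, queue)
  expect_equal(st$branches, branches)
})

test_that("frost defoliation is piecewise linear in minimum temperature", {
  tree <- make_tree()
  expect_equal(frost_defoliation(tree, 0)$fraction, 0)
  expect_equal(frost_defoliation(tree, -10.5)$fraction, 0.5)
  expect_equal(frost_defoliation(tree, -20)$fraction, 1)
  for (tmin in seq(-16, 0, 0.5)) {
    fr <- frost_defoliation(tree, tmin)
    expected <- min(1, max(0, (-7 - tmin) / 7))
    expect_equal(fr$fraction, expected, tolerance = 1e-12)
    expect_equal(fr$litter, expected * tree$leaves, tolerance = 1e-12)
  }
})

test_that("fine-root growth distribution weights volume and wetness", {
  zones <- list(make_zone(0.5, dz = c(0.3, 0.3), theta = c(0.23, 0.07)),
                make_zone(0.5, dz = c(0.3, 0.3), theta = c(0.23, 0.07)))
  inc <- distribute_fine_root_growth(10, zones)
  expect_equal(sum(inc), 10, tolerance = 1e-12)
  expect_equal(inc[, 2], c(0, 0))  # layers at wilting get nothing
  # uniform wetness and volume: equal split
  zu <- list(make_zone(0.5, dz = c(0.3, 0.3), theta = 0.2),
             make_zone(0.5, dz = c(0.3, 0.3), theta = 0.2))
  incu <- distribute_fine_root_growth(8, zu)
  expect_true(all(abs(incu - 2) < 1e-12))
  # all-dry fallback: volume-only weights
  zd <- list(make_zone(0.5, dz = c(0.3, 0.3), theta = 0.07),
             make_zone(0.5, dz = c(0.3, 0.3), theta = 0.07))
  incd <- distribute_fine_root_growth(8, zd)
  expect_equal(sum(incd), 8, tolerance = 1e-12)
})

test_that("root length density inverts the initialization mapping", {
  zones <- list(make_zone(0.9, dz = c(0.2, 0.3, 0.5)),
                make_zone(0.1, dz = c(0.2, 0.3, 0.5)))
  lv_target <- matrix(c(0.6, 0.4, 0.2, 0.6, 0.4, 0.2), 2, 3, byrow = TRUE)
  srl <- 12
  mass <- matrix(0, 2, 3)
  for (zi in 1:2) {
    mass[zi, ] <- lv_target[zi, ] * 1e4 * zones[[zi]]$layers$dz *
      zones[[zi]]$frac / srl
  }
  expect_equal(root_length_density(mass, zones, srl), lv_target,
               tolerance = 1e-12)
  expect_equal(root_length_density(2 * mass, zones, srl), 2 * lv_target,
               tolerance = 1e-12)
  expect_equal(root_length_density(0 * mass, zones, srl),
               matrix(0, 2, 3))
})

test_that("soil carbon pools conserve carbon and decay first-order", {
  sp <- default_soilc_params()
  empty <- soil_carbon_step(list(fresh = 0, humus = 0), 0, 20, 0.5, sp)
  expect_equal(empty$resp_h, 0)

  # fixed modifiers: pool follows discrete first-order decay
  pools <- list(fresh = 100, humus = 0)
  rate_eff <- sp$k_fresh * 1 * 1  # T = t_ref, wetness = 0.5 -> fmoist 1
  for (d in 1:20) pools <- soil_carbon_step(pools, 0, 20, 0.5, sp)$pools
  expect_equal(pools$fresh, 100 * (1 - rate_eff)^20, tolerance = 1e-9)

  set.seed(11)
  for (k in 1:20) {
    pools <- list(fresh = runif(1, 0, 200), humus = runif(1, 0, 5000))
    lit <- runif(1, 0, 10)
    before <- pools$fresh + pools$humus
    r <- soil_carbon_step(pools, lit, runif(1, 0, 35), runif(1), sp)
    after <- r$pools$fresh + r$pools$humus
    expect_lt(abs(before + lit - r$resp_h - after), 1e-9)
    expect_gte(r$resp_h, 0)
  }
})

test_that("ecosystem flux identities and sign conventions hold", {
  f <- ecosystem_fluxes(10, 2, 1, 3)
  expect_equal(f$resp_eco, 6)
  expect_equal(f$nee, -4)               # net sink is negative
  expect_equal(ecosystem_fluxes(0, 2, 1, 3)$nee, 6)  # pure respiration: source
  expect_equal(ecosystem_fluxes(6, 2, 1, 3)$nee, 0)
})
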