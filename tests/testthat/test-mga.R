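test_that("chromosome encoding is a fixed-width bijection on the grid", {
  expect_identical(length(encode_theta(c(90, 10), 241)), 14L)   # 8 + 6 bits
  g <- parameter_grid(61)
  for (i in seq_len(nrow(g))) {
    th <- c(g$mu[i], g$sigma[i])
    expect_identical(unname(decode_bits(encode_theta(th, 61), 61)),
                     as.integer(th))
  }
  expect_identical(sum(encode_theta(c(90, 10), 241) !=
                       encode_theta(c(90, 10), 241)), 0L)
})

test_that("initial populations are stratified, valid and reproducible", {
  ds <- fx_two()
  cfg <- mga_config(pop_size = 30, seed = 4)
  cache <- fitness_cache()
  set.seed(cfg$seed)
  p1 <- init_population(ds$W, cfg, cache = cache)
  set.seed(cfg$seed)
  p2 <- init_population(ds$W, cfg, cache = cache)
  expect_identical(p1, p2)
  expect_identical(length(p1), 30L)
  smax <- ceiling(101 / 6) - 1
  for (c_ in p1) {
    expect_true(c_$mu >= 1 && c_$mu <= 101)
    expect_true(c_$sigma >= 1 && c_$sigma <= smax)
  }
  # a single stratum degenerates to uniform sampling + top-k
  set.seed(1)
  p3 <- init_population(ds$W, cfg, n_subspaces = 1, cache = cache)
  expect_identical(length(p3), 30L)
})

test_that("area separation matches an independent greedy oracle", {
  t <- 241
  solo <- separate_areas(list(make_chrom(50, 10, t, 0.5)), r0 = 6)
  expect_identical(length(solo), 1L)
  expect_identical(solo[[1]]$radius, 0)

  far <- separate_areas(list(make_chrom(50, 10, t, 0.5),
                             make_chrom(120, 10, t, 0.7)), r0 = 6)
  expect_identical(length(far), 2L)
  expect_identical(lengths(lapply(far, `[[`, "members")), c(1L, 1L))

  set.seed(9)
  df <- data.frame(mu = sample(1:241, 30, TRUE),
                   sigma = sample(1:40, 30, TRUE),
                   fit = runif(30))
  pop <- lapply(seq_len(30), function(i)
    make_chrom(df$mu[i], df$sigma[i], t, df$fit[i]))
  areas <- separate_areas(pop, r0 = 15)
  oracle <- oracle_greedy_cluster(df, r0 = 15)
  expect_identical(length(areas), length(oracle))
  for (i in seq_along(areas)) {
    got <- sort(vapply(areas[[i]]$members, function(m)
      paste0(m$mu, "_", m$sigma, "_", m$fit), ""))
    want <- sort(paste0(oracle[[i]]$mu, "_", oracle[[i]]$sigma, "_",
                        oracle[[i]]$fit))
    expect_identical(got, want)
    # radius is the largest member distance from the centre
    dmax <- max(vapply(areas[[i]]$members, function(m)
      sqrt((m$mu - areas[[i]]$center$mu)^2 +
           (m$sigma - areas[[i]]$center$sigma)^2), 0))
    expect_identical(areas[[i]]$radius, dmax)
  }
})

test_that("mating crosses differing bits and filters children by fitness", {
  ds <- fx_five()
  cfg <- mga_config()
  # identical parents: no differing bits, no children
  dup <- list(center = make_chrom(90, 10, 241, 1),
              radius = 0,
              members = list(make_chrom(90, 10, 241, 1),
                             make_chrom(90, 10, 241, 1)))
  expect_identical(mate_and_reproduce(dup, cfg, ds$W, cache = ds$cache),
                   list())

  mk <- function(mu, sg) make_chrom(mu, sg, 241,
                                    picarc_fitness(c(mu, sg), ds$W,
                                                   cache = ds$cache))
  area <- list(center = mk(88, 11), radius = 5,
               members = list(mk(88, 11), mk(92, 9), mk(86, 13)))
  kids <- mate_and_reproduce(area, cfg, ds$W, cache = ds$cache)
  worst_parent <- max(vapply(area$members, `[[`, 0, "fit"))
  for (k in kids) {
    expect_lt(k$fit, worst_parent)
    expect_no_error(reference_params(k$mu, k$sigma, 241))
  }
})

test_that("emigrant selection is an exhaustive disjoint split by fitness", {
  t <- 241
  mem <- lapply(1:7, function(i) make_chrom(80 + i, 10, t, i / 10))
  area <- list(center = mem[[1]], radius = 6, members = mem)
  sp <- select_emigrants(area, keep = 3)
  expect_identical(length(sp$stay), 3L)
  expect_identical(length(sp$emigrants), 4L)
  all_back <- c(sp$stay, sp$emigrants)
  expect_setequal(vapply(all_back, `[[`, 0, "fit"),
                  vapply(mem, `[[`, 0, "fit"))
  expect_lt(max(vapply(sp$stay, `[[`, 0, "fit")),
            min(vapply(sp$emigrants, `[[`, 0, "fit")))

  expect_identical(length(select_emigrants(area, keep = 10)$emigrants), 0L)
  expect_identical(length(select_emigrants(area, keep = 1)$stay), 1L)
})

test_that("immigrant quotas favour elite-poor areas and conserve totals", {
  t <- 241
  mk_area <- function(mu, sg, radius, ne)
    list(center = make_chrom(mu, sg, t, 0.1), radius = radius,
         members = list(), num_elites = ne)
  cfg <- mga_config()
  a <- list(mk_area(50, 20, 2, 23), mk_area(150, 10, 2, 1))
  al <- allocate_immigrants(a, total_quota = 12, cfg, t)
  expect_identical(sum(al$quota), 12L)
  q <- setNames(al$quota, vapply(al$area_ids, `[[`, 0L, 1))
  expect_gt(q[["2"]], q[["1"]])                     # fewer elites, more quota

  # three mutually overlapping areas merge transitively into one group
  b <- list(mk_area(100, 20, 10, 2), mk_area(104, 20, 10, 2),
            mk_area(108, 20, 10, 2))
  al2 <- allocate_immigrants(b, total_quota = 9, cfg, t)
  expect_identical(nrow(al2), 1L)
  expect_identical(sum(al2$quota), 9L)
  centers <- list(c(100, 20), c(104, 20), c(108, 20))
  expect_identical(length(unique(oracle_overlap_groups(
    centers, c(10, 10, 10), cfg$overlap_merge_factor))), 1L)

  # boundary areas are excluded; all-boundary means no allocation
  c_ <- list(mk_area(1, 20, 2, 0), mk_area(150, 40, 2, 0))
  expect_identical(nrow(allocate_immigrants(c_, 5, cfg, t)), 0L)
  d_ <- list(mk_area(1, 20, 2, 5), mk_area(150, 10, 2, 5))
  al3 <- allocate_immigrants(d_, 5, cfg, t)
  expect_identical(nrow(al3), 1L)
  expect_identical(al3$area_ids[[1]], 2L)
})

test_that("solution screening keeps only interior verified minima", {
  ds <- fx_five()
  centers <- list(make_chrom(90, 10, 241, 0),       # true minimum
                  make_chrom(90, 11, 241, 0),       # its neighbour: not one
                  make_chrom(120, 40, 241, 0),      # sigma boundary
                  make_chrom(90, 10, 241, 0))       # duplicate
  sols <- find_solutions(centers, ds$W, cache = ds$cache)
  expect_identical(theta_matrix(sols),
                   matrix(c(90L, 10L), 1))
})

test_that("a full run is deterministic and conserves the population", {
  ds <- fx_two()
  cfg <- mga_config(seed = 6)
  r1 <- suppressWarnings(mga_run(ds$X, cfg))
  r2 <- suppressWarnings(mga_run(ds$X, cfg))
  expect_identical(theta_matrix(r1$solutions), theta_matrix(r2$solutions))
  expect_identical(r1$history, r2$history)

  per_gen <- tapply(r1$history$NumP, r1$history$Generation, sum)
  expect_true(all(per_gen == cfg$pop_size))
})

test_that("a lone compound yields exactly one solution at its parameters", {
  ds <- fx_one()
  res <- suppressWarnings(mga_run(ds$X, mga_config(seed = 2)))
  expect_identical(theta_matrix(res$solutions),
                   matrix(c(30L, 5L), 1))
})

test_that("area radii shrink as the search converges", {
  ds <- fx_five()
  shrunk <- vapply(1:3, function(sd) {
    h <- suppressWarnings(mga_run(ds$X, mga_config(seed = sd)))$history
    mean(h$Radius[h$Generation == max(h$Generation)]) <
      mean(h$Radius[h$Generation == 1])
  }, TRUE)
  expect_true(all(shrunk))
})
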