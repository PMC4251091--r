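#' Configuration of the multi-areas genetic algorithm
#'
#' The search looks for all interior local minima of the fitness surface
#' over the integer (mu, sigma) grid simultaneously, by clustering the
#' population into circular "areas" in the mu-sigma plane and evolving
#' each area on its own.
#'
#' @param pop_size total population size (default 60).
#' @param n_subspaces number of equal mu-axis strata used when drawing
#'   the initial population (default 6).
#' @param n_elites_per_area number of members per area that mate each
#'   generation (default 5).
#' @param keep_per_area members kept per area after reproduction; the
#'   rest emigrate and are replaced by immigrants (default 3).
#' @param initial_radius the user-defined radius used when an area is
#'   first drawn around its centre, in Euclidean (mu, sigma) units
#'   (default 6; updated radii observed in practice stay below it).
#' @param radius_stop_threshold an area reproduces only while its radius
#'   exceeds this (default 1).
#' @param overlap_merge_factor two areas are merged for immigration when
#'   their centre distance is below this factor times the sum of their
#'   radii (default 0.5).
#' @param max_generations hard cap on generations (default 50).
#' @param strict_child_filter keep a child only if it beats both parents
#'   (TRUE, default) or just the worse parent (FALSE).  The weak filter
#'   accepts children that merely beat a freshly immigrated parent, so
#'   evolution essentially never stalls and runs always hit
#'   \code{max_generations}; the strict filter reproduces the expected
#'   ~10-20 generation convergence.
#' @param seed integer RNG seed; the whole run is reproducible given it.
#' @return list of class \code{mga_config}.
#' @export
mga_config <- function(pop_size = 60L, n_subspaces = 6L,
                       n_elites_per_area = 5L, keep_per_area = 3L,
                       initial_radius = 6, radius_stop_threshold = 1,
                       overlap_merge_factor = 0.5, max_generations = 50L,
                       strict_child_filter = TRUE, seed = 1L) {
  cfg <- list(pop_size = as.integer(pop_size),
              n_subspaces = as.integer(n_subspaces),
              n_elites_per_area = as.integer(n_elites_per_area),
              keep_per_area = as.integer(keep_per_area),
              initial_radius = initial_radius,
              radius_stop_threshold = radius_stop_threshold,
              overlap_merge_factor = overlap_merge_factor,
              max_generations = as.integer(max_generations),
              strict_child_filter = isTRUE(strict_child_filter),
              seed = as.integer(seed))
  stopifnot(cfg$pop_size >= 2, cfg$n_subspaces >= 1,
            cfg$n_elites_per_area >= 1, cfg$keep_per_area >= 1,
            cfg$initial_radius > 0, cfg$radius_stop_threshold >= 0,
            cfg$overlap_merge_factor > 0, cfg$max_generations >= 1)
  structure(cfg, class = "mga_config")
}

# ---- chromosome encoding ---------------------------------------------

bit_widths <- function(t) {
  c(mu = ceiling(log2(t)), sigma = ceiling(log2(sigma_max(t))))
}

int_to_bits <- function(x, width) {
  as.integer(bitwAnd(bitwShiftR(x, (width - 1L):0L), 1L))
}

bits_to_int <- function(bits) {
  as.integer(sum(bits * 2^((length(bits) - 1L):0L)))
}

#' Encode a (mu, sigma) pair as a fixed-width bit string
#'
#' Plain binary, mu first then sigma, with widths
#' \code{ceiling(log2(t))} and \code{ceiling(log2(sigma_max))} bits
#' (values stored zero-based).
#'
#' @param theta a \code{\link{reference_params}} or c(mu, sigma).
#' @param t time-axis length.
#' @return integer vector of 0/1 bits.
#' @export
encode_theta <- function(theta, t) {
  if (!inherits(theta, "reference_params"))
    theta <- reference_params(theta[[1]], theta[[2]], t)
  w <- bit_widths(t)
  c(int_to_bits(theta$mu - 1L, w["mu"]),
    int_to_bits(theta$sigma - 1L, w["sigma"]))
}

#' Decode a bit string back to c(mu, sigma)
#'
#' The decoded pair may fall outside the admissible grid (binary widths
#' cover a power of two); callers must validate with the grid bounds.
#'
#' @param bits integer 0/1 vector as produced by \code{\link{encode_theta}}.
#' @param t time-axis length.
#' @return integer c(mu, sigma), not validated.
#' @export
decode_bits <- function(bits, t) {
  w <- bit_widths(t)
  if (length(bits) != sum(w))
    stop("bit string length ", length(bits), ", expected ", sum(w))
  c(mu = bits_to_int(bits[seq_len(w["mu"])]) + 1L,
    sigma = bits_to_int(bits[w["mu"] + seq_len(w["sigma"])]) + 1L)
}

new_chromosome <- function(mu, sigma, t, fit) {
  list(mu = as.integer(mu), sigma = as.integer(sigma),
       bits = encode_theta(c(mu, sigma), t), fit = fit)
}

# Ordering used everywhere ties must break reproducibly:
# fitness, then mu, then sigma.
order_chromosomes <- function(pop) {
  pop[order(vapply(pop, `[[`, 0, "fit"),
            vapply(pop, `[[`, 0L, "mu"),
            vapply(pop, `[[`, 0L, "sigma"))]
}

chrom_dist <- function(a, b) {
  sqrt((a$mu - b$mu)^2 + (a$sigma - b$sigma)^2)
}

hamming <- function(a, b) sum(a$bits != b$bits)

# ---- population initialisation ---------------------------------------

#' Draw the initial population
#'
#' The mu axis is split into \code{n_subspaces} equal strata;
#' \code{cfg$pop_size} chromosomes are drawn uniformly at random inside
#' every stratum (sigma uniform over its full range), and the best
#' \code{cfg$pop_size} of all draws by fitness form the initial
#' population.
#'
#' @param W a \code{\link{center_whiten}} result.
#' @param cfg an \code{\link{mga_config}}.
#' @param n_subspaces stratum count (defaults to \code{cfg$n_subspaces}).
#' @param opts a \code{\link{fit_options}}.
#' @param cache a \code{\link{fitness_cache}}.
#' @return list of chromosomes sorted by fitness.
#' @export
init_population <- function(W, cfg, n_subspaces = cfg$n_subspaces,
                            opts = fit_options(), cache = fitness_cache()) {
  t <- W$t
  smax <- sigma_max(t)
  edges <- round(seq(0L, t, length.out = n_subspaces + 1L))
  pop <- list()
  for (s in seq_len(n_subspaces)) {
    lo <- edges[s] + 1L
    hi <- max(edges[s + 1L], lo)
    mus <- sample(lo:hi, cfg$pop_size, replace = TRUE)
    sgs <- sample(seq_len(smax), cfg$pop_size, replace = TRUE)
    for (i in seq_len(cfg$pop_size)) {
      fit <- picarc_fitness(c(mus[i], sgs[i]), W, opts, cache)
      pop[[length(pop) + 1L]] <- new_chromosome(mus[i], sgs[i], t, fit)
    }
  }
  order_chromosomes(pop)[seq_len(cfg$pop_size)]
}

# ---- area clustering --------------------------------------------------

#' Greedy clustering of a population into areas
#'
#' Repeatedly: the unassigned chromosome with the best fitness becomes
#' the centre of a new area; every unassigned chromosome within the
#' user-defined radius \code{r0} of it joins; the area's radius is then
#' updated to the largest member distance.  Every chromosome ends up in
#' exactly one area.
#'
#' @param pop list of chromosomes.
#' @param r0 the drawing radius, Euclidean in (mu, sigma) units.
#' @return list of areas: each a list with \code{center} (chromosome),
#'   \code{radius}, \code{members} (chromosome list sorted by fitness).
#' @export
separate_areas <- function(pop, r0) {
  if (!length(pop)) stop("empty population")
  pop <- order_chromosomes(pop)
  unassigned <- rep(TRUE, length(pop))
  areas <- list()
  while (any(unassigned)) {
    ci <- which(unassigned)[1L]   # best fitness among unassigned
    center <- pop[[ci]]
    idx <- which(unassigned)
    d <- vapply(idx, function(j) chrom_dist(center, pop[[j]]), 0)
    take <- idx[d <= r0]
    radius <- max(d[d <= r0])
    unassigned[take] <- FALSE
    areas[[length(areas) + 1L]] <-
      list(center = center, radius = radius, members = pop[take])
  }
  areas
}

area_at_boundary <- function(area, t) {
  smax <- sigma_max(t)
  c_ <- area$center
  c_$mu %in% c(1L, t) || c_$sigma %in% c(1L, smax)
}

# ---- reproduction -----------------------------------------------------

#' Mate elites of an area and keep the excellent children
#'
#' The top \code{cfg$n_elites_per_area} members mate, each with the area
#' member at maximal Hamming distance from it (ties resolved by fitness
#' order).  One child is generated per differing bit position: the elite
#' with that bit copied from the mate.  A child is kept only if it
#' decodes to an admissible grid point and its fitness beats the worse
#' parent (both parents if \code{cfg$strict_child_filter}).
#'
#' @param area an area from \code{\link{separate_areas}}.
#' @param cfg an \code{\link{mga_config}}.
#' @param W,opts,cache fitness evaluation context.
#' @return list of accepted child chromosomes (possibly empty).
#' @export
mate_and_reproduce <- function(area, cfg, W, opts = fit_options(),
                               cache = fitness_cache()) {
  members <- order_chromosomes(area$members)
  if (length(members) < 2L) return(list())
  t <- W$t
  smax <- sigma_max(t)
  n_el <- min(cfg$n_elites_per_area, length(members))
  children <- list()
  for (ei in seq_len(n_el)) {
    elite <- members[[ei]]
    hd <- vapply(members, function(m) hamming(elite, m), 0)
    mate <- members[[which.max(hd)]]   # ties: first in fitness order
    diffpos <- which(elite$bits != mate$bits)
    worse_fit <- max(elite$fit, mate$fit)
    gate <- if (cfg$strict_child_filter) min(elite$fit, mate$fit) else worse_fit
    for (p in diffpos) {
      bits <- elite$bits
      bits[p] <- mate$bits[p]
      th <- decode_bits(bits, t)
      if (th[1] < 1L || th[1] > t || th[2] < 1L || th[2] > smax) next
      fit <- picarc_fitness(th, W, opts, cache)
      if (fit < gate)
        children[[length(children) + 1L]] <- new_chromosome(th[1], th[2], t, fit)
    }
  }
  children
}

#' Split an area into stayers and emigrants
#'
#' The top \code{keep} members by fitness stay; everyone else emigrates
#' (their slots are refilled by immigrants elsewhere).
#'
#' @param area an area.
#' @param keep number of members that stay (>= 1).
#' @return list with \code{stay} and \code{emigrants}, a disjoint
#'   exhaustive split of the members.
#' @export
select_emigrants <- function(area, keep) {
  stopifnot(keep >= 1)
  members <- order_chromosomes(area$members)
  n <- length(members)
  k <- min(keep, n)
  list(stay = members[seq_len(k)],
       emigrants = if (n > k) members[(k + 1L):n] else list())
}

# ---- immigration ------------------------------------------------------

# Transitive closure of the pairwise overlap relation.
overlap_groups <- function(areas, factor) {
  n <- length(areas)
  if (!n) return(integer())
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      d <- chrom_dist(areas[[i]]$center, areas[[j]]$center)
      if (d < factor * (areas[[i]]$radius + areas[[j]]$radius))
        adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  group <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      g <- min(group[adj[i, ]])
      if (g < group[i]) { group[group == group[i]] <- g; changed <- TRUE }
    }
    if (!changed) break
  }
  match(group, sort(unique(group)))
}

#' Allocate immigrant quotas to merged area groups
#'
#' Areas whose centre lies on the boundary of the mu-sigma domain are
#' excluded.  Remaining areas whose centres are closer than
#' \code{overlap_merge_factor} times the sum of their radii are merged
#' (transitively) into one receiving group, so an overlap cannot double
#' a region's quota.  Each group's quota is proportional to
#' \code{1 / (1 + elite count)} — areas that already hold many elites
#' receive fewer newcomers — rounded by largest remainder so the quotas
#' sum exactly to \code{total_quota}.
#'
#' @param areas list of areas; each may carry a \code{num_elites} field
#'   (defaults to 0 when absent).
#' @param total_quota number of immigrants to allocate.
#' @param cfg an \code{\link{mga_config}}.
#' @param t time-axis length (for the boundary rule).
#' @return data.frame with one row per receiving group: \code{group},
#'   \code{quota}, \code{area_ids} (list column of indices into
#'   \code{areas}).  Zero rows when every area is at the boundary.
#' @export
allocate_immigrants <- function(areas, total_quota, cfg, t) {
  stopifnot(total_quota >= 0)
  eligible <- which(!vapply(areas, area_at_boundary, TRUE, t = t))
  if (!length(eligible))
    return(data.frame(group = integer(), quota = integer(),
                      area_ids = I(list())))
  sub <- areas[eligible]
  grp <- overlap_groups(sub, cfg$overlap_merge_factor)
  ids <- split(eligible, grp)
  ne <- vapply(ids, function(ii) sum(vapply(areas[ii], function(a)
    if (is.null(a$num_elites)) 0 else as.numeric(a$num_elites), 0)), 0)
  wt <- 1 / (1 + ne)
  raw <- total_quota * wt / sum(wt)
  quota <- floor(raw)
  rem <- total_quota - sum(quota)
  if (rem > 0) {
    extra <- order(raw - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1L
  }
  data.frame(group = seq_along(ids), quota = as.integer(quota),
             area_ids = I(unname(ids)))
}

# Bounding circle of a merged group: centred on the best area centre,
# radius reaching every member area's far edge.  Floored at sqrt(2) so a
# fully collapsed area still probes its eight grid neighbours, but never
# re-inflated to the initial drawing radius: immigrant circles must
# shrink with their areas or the radii would never fall below the stop
# threshold and the run would not terminate.
group_circle <- function(areas, ids) {
  centers <- lapply(areas[ids], `[[`, "center")
  best <- order_chromosomes(centers)[[1L]]
  rad <- max(vapply(ids, function(i)
    chrom_dist(best, areas[[i]]$center) + areas[[i]]$radius, 0))
  list(mu = best$mu, sigma = best$sigma, radius = max(rad, sqrt(2)))
}

# Generate-and-select immigrants for one group: draw cfg$pop_size
# candidates uniformly in the group's bounding circle (clipped to the
# grid), keep the best `quota` by fitness.  Draws landing outside the
# circle are redrawn (bounded rounds) so small circles still fill their
# quota and the population size is conserved.
generate_immigrants <- function(circle, quota, cfg, W, opts, cache) {
  if (quota <= 0L) return(list())
  t <- W$t
  smax <- sigma_max(t)
  R <- ceiling(circle$radius)
  mu_rng <- max(1L, circle$mu - R):min(t, circle$mu + R)
  sg_rng <- max(1L, circle$sigma - R):min(smax, circle$sigma + R)
  mus <- integer(0); sgs <- integer(0)
  for (round in seq_len(10L)) {
    m <- sample(mu_rng, cfg$pop_size, replace = TRUE)
    s <- sample(sg_rng, cfg$pop_size, replace = TRUE)
    keep <- (m - circle$mu)^2 + (s - circle$sigma)^2 <= circle$radius^2
    mus <- c(mus, m[keep]); sgs <- c(sgs, s[keep])
    if (length(mus) >= max(quota, cfg$pop_size)) break
  }
  if (!length(mus)) { mus <- circle$mu; sgs <- circle$sigma }
  cand <- lapply(seq_along(mus), function(i)
    new_chromosome(mus[i], sgs[i], t,
                   picarc_fitness(c(mus[i], sgs[i]), W, opts, cache)))
  cand <- order_chromosomes(cand)
  cand[seq_len(min(quota, length(cand)))]
}

# ---- solution screening -----------------------------------------------

#' Screen candidate centres for verified grid local minima
#'
#' A candidate theta is accepted as a solution when it is strictly
#' interior to the mu-sigma domain and its fitness is no worse than that
#' of all eight grid neighbours.  Duplicate candidates collapse to one.
#'
#' @param centers list of chromosomes (or of \code{reference_params}).
#' @param W a \code{\link{center_whiten}} result.
#' @param opts a \code{\link{fit_options}}.
#' @param cache a \code{\link{fitness_cache}}.
#' @return list of \code{\link{reference_params}}, sorted by ascending mu.
#' @export
find_solutions <- function(centers, W, opts = fit_options(),
                           cache = fitness_cache()) {
  t <- W$t
  smax <- sigma_max(t)
  seen <- character()
  sols <- list()
  for (c_ in centers) {
    mu <- c_$mu; sg <- c_$sigma
    key <- paste0(mu, "_", sg)
    if (key %in% seen) next
    seen <- c(seen, key)
    if (mu %in% c(1L, t) || sg %in% c(1L, smax)) next
    f0 <- picarc_fitness(c(mu, sg), W, opts, cache)
    ok <- TRUE
    for (dm in -1:1) for (ds in -1:1) {
      if (dm == 0 && ds == 0) next
      if (f0 > picarc_fitness(c(mu + dm, sg + ds), W, opts, cache)) {
        ok <- FALSE; break
      }
    }
    if (ok) sols[[length(sols) + 1L]] <- reference_params(mu, sg, t)
  }
  mus <- vapply(sols, `[[`, 0L, "mu")
  sgs <- vapply(sols, `[[`, 0L, "sigma")
  sols[order(mus, sgs)]
}

# ---- main loop --------------------------------------------------------

#' Run the multi-areas genetic algorithm on a chromatogram
#'
#' Whitens the data once, draws a stratified initial population, then
#' loops: cluster the population into areas, let every area whose radius
#' is still large enough reproduce (excellent children replace the worst
#' members, area size preserved), keep only the best few members per
#' area, and refill the freed slots with immigrants allocated to merged,
#' non-boundary area groups.  The loop ends when no area can reproduce
#' (all radii at or below the stop threshold) or after
#' \code{max_generations}; final area centres are then screened for
#' verified grid local minima.
#'
#' @param X a \code{\link{chromatogram}} (or bare matrix).
#' @param cfg an \code{\link{mga_config}}.
#' @param fit_opts a \code{\link{fit_options}}.
#' @return object of class \code{mga_result}: \code{solutions} (list of
#'   \code{\link{reference_params}}), \code{areas_final},
#'   \code{generations}, \code{history} (per-generation area table with
#'   columns Generation, AreaId, CenterMu, CenterSigma, Radius, NumE,
#'   NumP, BestFit), \code{converged}, \code{cache}, \code{W},
#'   \code{fit_opts}, \code{cfg}.
#' @export
mga_run <- function(X, cfg = mga_config(), fit_opts = fit_options()) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(cfg$seed)

  W <- center_whiten(X)
  t <- W$t
  cache <- fitness_cache()
  pop <- init_population(W, cfg, opts = fit_opts, cache = cache)

  history <- list()
  converged <- FALSE
  gen <- 0L
  areas <- separate_areas(pop, cfg$initial_radius)

  annotate_elites <- function(areas, pop) {
    # an area's elite count: members in the top half of the population
    cut <- max(1L, length(pop) %/% 2L)
    elite_fit <- order_chromosomes(pop)[[cut]]$fit
    lapply(areas, function(a) {
      a$num_elites <- sum(vapply(a$members, `[[`, 0, "fit") <= elite_fit)
      a$num_pop <- length(a$members)
      a
    })
  }

  for (gen in seq_len(cfg$max_generations)) {
    areas <- annotate_elites(areas, pop)
    for (ai in seq_along(areas)) {
      a <- areas[[ai]]
      history[[length(history) + 1L]] <- data.frame(
        Generation = gen, AreaId = ai,
        CenterMu = a$center$mu, CenterSigma = a$center$sigma,
        Radius = a$radius, NumE = a$num_elites, NumP = a$num_pop,
        BestFit = a$center$fit)
    }

    can_reproduce <- vapply(areas, function(a)
      a$radius > cfg$radius_stop_threshold && length(a$members) >= 2L, TRUE)
    if (!any(can_reproduce)) { converged <- TRUE; break }

    n_children <- 0L
    for (ai in which(can_reproduce)) {
      children <- mate_and_reproduce(areas[[ai]], cfg, W, fit_opts, cache)
      n_children <- n_children + length(children)
      if (length(children)) {
        size <- length(areas[[ai]]$members)
        merged <- order_chromosomes(c(areas[[ai]]$members, children))
        areas[[ai]]$members <- merged[seq_len(size)]
      }
    }
    # evolution has stalled when no area produced an excellent child:
    # every remaining area sits at its optimum, so stop even if some
    # radii are still above the threshold
    if (n_children == 0L) { converged <- TRUE; break }

    stays <- list()
    n_emigrants <- 0L
    for (ai in seq_along(areas)) {
      split_ <- select_emigrants(areas[[ai]], cfg$keep_per_area)
      stays <- c(stays, split_$stay)
      n_emigrants <- n_emigrants + length(split_$emigrants)
    }

    alloc <- allocate_immigrants(areas, n_emigrants, cfg, t)
    immigrants <- list()
    if (nrow(alloc)) {
      for (gi in seq_len(nrow(alloc))) {
        circle <- group_circle(areas, alloc$area_ids[[gi]])
        immigrants <- c(immigrants,
                        generate_immigrants(circle, alloc$quota[gi], cfg,
                                            W, fit_opts, cache))
      }
    }
    pop <- c(stays, immigrants)
    areas <- separate_areas(pop, cfg$initial_radius)
  }

  areas <- annotate_elites(areas, pop)
  solutions <- find_solutions(lapply(areas, `[[`, "center"), W,
                              fit_opts, cache)
  if (!converged)
    warning("multi-areas GA hit max_generations = ", cfg$max_generations,
            " before all area radii shrank below the stop threshold")
  structure(
    list(solutions = solutions, areas_final = areas,
         generations = gen,
         history = do.call(rbind, history),
         converged = converged, cache = cache, W = W,
         fit_opts = fit_opts, cfg = cfg),
    class = "mga_result")
}

#' @export
print.mga_result <- function(x, ...) {
  cat("<mga_result> ", x$generations, " generations, ",
      length(x$solutions), " solution(s):\n", sep = "")
  for (s in x$solutions)
    cat("  (mu = ", s$mu, ", sigma = ", s$sigma, ")\n", sep = "")
  invisible(x)
}
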