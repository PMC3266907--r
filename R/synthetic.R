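# Seeded generators for every input the pipeline consumes: trees with deep
# Yule (between-species) divergences and shallow coalescent (within-species)
# structure, JC69 alignments, smooth latitudinal SST rasters with a seasonal
# amplitude, and occurrence records confined to a thermal niche.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!requireNamespace("withr", quietly = TRUE)) {
    set.seed(seed)
    return(force(code))
  }
  withr::with_seed(seed, code)
}

#' Simulate a species tree with within-species coalescent structure
#'
#' Draws a Yule species tree conditioned on `k` tips (pure birth, rate
#' `lambda`), then grafts onto each species tip a Kingman coalescent
#' genealogy of `m` samples (pairwise coalescence rate `n(n-1)/(2*theta)`).
#' The within-species subtrees are rescaled so that the deepest coalescence
#' equals the shallowest species divergence divided by the separation factor
#' `s`, guaranteeing an identifiable threshold between the two processes at
#' large `s` and hard cases at `s` near 1.
#'
#' @param k number of species (>= 1; `k = 1` returns a pure coalescent
#'   tree).
#' @param m samples per species (>= 1).
#' @param lambda Yule speciation rate per branch-length unit. Default 20,
#'   giving species-tree depths of a few hundredths of a substitution/site,
#'   the scale of a plastid marker in brown algae.
#' @param theta within-species coalescent scale (expected pairwise
#'   coalescence time for two lineages), same units.
#' @param s separation factor: (shallowest species divergence) /
#'   (deepest within-species coalescence). Must be > 0.
#' @param seed integer seed; identical seeds give byte-identical newick.
#' @return list with `tree` (an `ultratree`), `species` (named character
#'   vector tip label -> species id), `k`, `m` and `true_N = k`.
#' @export
simulate_gmyc_tree <- function(k, m, lambda = 20, theta = 0.005, s = 10,
                               seed = NULL) {
  stopifnot(k >= 1L, m >= 1L, s > 0, lambda > 0, theta > 0)
  if (k == 1L && m < 2L) stop("a one-species tree needs m >= 2", call. = FALSE)
  with_seed(seed, {
    wid <- max(3L, nchar(as.character(k)))
    sp_lab <- sprintf(paste0("SP%0", wid, "d"), seq_len(k))
    coal_sub <- lapply(seq_len(k), function(i) {
      if (m == 1L) return(NULL)
      sub <- ape::rcoal(m, tip.label = sprintf("%s_T%03d", sp_lab[i],
                                               seq_len(m)))
      sub$edge.length <- sub$edge.length * theta
      sub
    })
    if (k == 1L) {
      tree <- as_ultrametric(coal_sub[[1L]])
      species <- stats::setNames(rep(sp_lab, m), tree$tip.label)
      return(list(tree = tree, species = species, k = k, m = m, true_N = 1L))
    }
    sp_tree <- ape::rphylo(k, birth = lambda, death = 0)
    sp_tree$tip.label <- sp_lab
    sp_nd <- node_depths(as_ultrametric(sp_tree))
    d_min <- min(sp_nd[(k + 1L):(k + sp_tree$Nnode)])
    if (m > 1L) {
      c_max <- max(vapply(coal_sub, function(z) max(node_depths(
        as_ultrametric(z))), numeric(1)))
      f <- (d_min / s) / c_max
      coal_sub <- lapply(coal_sub, function(z) {
        z$edge.length <- z$edge.length * f
        z
      })
    }
    txt <- ape::write.tree(sp_tree, digits = 12)
    for (i in seq_len(k)) {
      if (m == 1L) {
        txt <- sub(paste0(sp_lab[i], ":"),
                   paste0(sp_lab[i], "_T001:"), txt, fixed = TRUE)
        next
      }
      sub <- coal_sub[[i]]
      c_i <- max(node_depths(as_ultrametric(sub)))
      sub_txt <- sub(";$", "", ape::write.tree(sub, digits = 12))
      # tip pendant length P_i is the full label:length token in txt
      pat <- paste0(sp_lab[i], ":")
      pos <- regexpr(pat, txt, fixed = TRUE)
      rest <- substring(txt, pos + nchar(pat))
      len_tok <- regmatches(rest, regexpr("^[0-9.eE+-]+", rest))
      P_i <- as.numeric(len_tok)
      stem <- P_i - c_i
      if (stem < 0) stop("internal error: negative graft stem", call. = FALSE)
      txt <- sub(paste0(pat, len_tok),
                 paste0(sub_txt, ":", format(stem, digits = 12)),
                 txt, fixed = TRUE)
    }
    tree <- parse_newick(txt, epsilon = 1e-5)
    species <- stats::setNames(sub("_T[0-9]+$", "", tree$tip.label),
                               tree$tip.label)
    list(tree = tree, species = species, k = k, m = m, true_N = as.integer(k))
  })
}

#' Simulate sequences along a tree under JC69
#'
#' Substitutions are Poisson with expectation `rate * branch length` per
#' site (Jukes-Cantor: equal base frequencies and exchange rates).
#'
#' @param tree an `ultratree` or `phylo`.
#' @param length alignment length in sites.
#' @param rate substitutions per unit branch length (1 if branch lengths are
#'   already in substitutions/site).
#' @param seed integer seed.
#' @return a `dna_alignment` (see [read_fasta()]).
#' @export
simulate_sequences <- function(tree, length = 500L, rate = 1, seed = NULL) {
  stopifnot(length >= 1L, rate >= 0)
  with_seed(seed, {
    if (rate == 0) {
      m <- matrix("A", nrow = length(tree$tip.label), ncol = length,
                  dimnames = list(tree$tip.label, NULL))
      return(new_alignment(m))
    }
    sim <- phangorn::simSeq(tree, l = length, rate = rate)
    m <- toupper(as.character(sim))
    new_alignment(m)
  })
}

#' Simulate min/mean/max SST raster layers
#'
#' The climatological mean follows a smooth equator-to-pole gradient,
#' `mean(lat) = T_eq - deltaT * (|lat|/90)^2`, with a seasonal amplitude
#' `A(lat) = A0 * |lat|/90` growing toward the poles; `min = mean - A` and
#' `max = mean + A`, so the layer ordering holds by construction. Cell-wise
#' Gaussian noise (sd `sigma`) perturbs the mean field and (symmetrically)
#' the amplitude before the layers are formed. Rectangles of land are set
#' to the nodata value in all three layers.
#'
#' @param nrows,ncols grid dimensions (row 1 is the northernmost row).
#' @param cellsize cell size in decimal degrees.
#' @param xll,yll lower-left corner of the grid (degrees).
#' @param T_eq equatorial mean SST, deg C.
#' @param deltaT equator-to-pole drop of the mean, deg C (>= 0).
#' @param A0 seasonal amplitude coefficient, deg C at the pole (>= 0).
#' @param sigma cell noise standard deviation, deg C (>= 0).
#' @param land list of rectangles `c(lat_min, lat_max, lon_min, lon_max)`
#'   masked as nodata.
#' @param nodata nodata value written for land cells.
#' @param seed integer seed.
#' @return an `sst_raster` (see [read_ascii_grid()]).
#' @export
simulate_sst_raster <- function(nrows = 60L, ncols = 120L, cellsize = 3,
                                xll = -180, yll = -90, T_eq = 28,
                                deltaT = 30, A0 = 12, sigma = 0.5,
                                land = list(), nodata = -9999,
                                seed = NULL) {
  stopifnot(deltaT >= 0, A0 >= 0, sigma >= 0)
  with_seed(seed, {
    lat_c <- yll + (rev(seq_len(nrows)) - 0.5) * cellsize  # row 1 = north
    lon_c <- xll + (seq_len(ncols) - 0.5) * cellsize
    latm <- matrix(lat_c, nrows, ncols)
    base <- T_eq - deltaT * (abs(latm) / 90)^2
    amp <- A0 * abs(latm) / 90
    noise_m <- matrix(stats::rnorm(nrows * ncols, 0, sigma), nrows, ncols)
    noise_a <- matrix(stats::rnorm(nrows * ncols, 0, sigma), nrows, ncols)
    mean_l <- base + noise_m
    amp <- abs(amp + noise_a)
    min_l <- mean_l - amp
    max_l <- mean_l + amp
    valid <- matrix(TRUE, nrows, ncols)
    lonm <- matrix(lon_c, nrows, ncols, byrow = TRUE)
    for (r in land) {
      valid[latm >= r[1L] & latm <= r[2L] &
            lonm >= r[3L] & lonm <= r[4L]] <- FALSE
    }
    min_l[!valid] <- mean_l[!valid] <- max_l[!valid] <- NA_real_
    new_sst_raster(nrows = nrows, ncols = ncols, cellsize = cellsize,
                   xll = xll, yll = yll, nodata = nodata,
                   min = min_l, mean = mean_l, max = max_l)
  })
}

#' Simulate occurrence records confined to a thermal niche
#'
#' Samples `n` cell-center points uniformly from the raster cells whose
#' minimum SST is at least `niche[1]` and maximum SST at most `niche[2]`
#' (optionally restricted to a lat/lon window), emulating a species whose
#' realized distribution tracks its thermal tolerance.
#'
#' @param raster an `sst_raster`.
#' @param species species id for the records.
#' @param niche numeric pair `c(lower, upper)` in deg C.
#' @param n number of records.
#' @param window optional `c(lat_min, lat_max, lon_min, lon_max)` restriction.
#' @param replace sample cells with replacement (default `TRUE`; with
#'   `FALSE` an error is raised if fewer suitable cells than `n` exist).
#' @param provenance provenance tag for the records.
#' @param seed integer seed.
#' @return data.frame `species`, `lat`, `lon`, `provenance`.
#' @export
simulate_occurrences <- function(raster, species, niche, n, window = NULL,
                                 replace = TRUE, provenance = "dna",
                                 seed = NULL) {
  stopifnot(inherits(raster, "sst_raster"), length(niche) == 2L, n >= 1L)
  with_seed(seed, {
    cc <- raster_cell_centers(raster)
    ok <- !is.na(raster$min) & !is.na(raster$max) &
      raster$min >= niche[1L] & raster$max <= niche[2L]
    if (!is.null(window)) {
      ok <- ok & cc$lat >= window[1L] & cc$lat <= window[2L] &
        cc$lon >= window[3L] & cc$lon <= window[4L]
    }
    idx <- which(ok)
    if (!length(idx)) stop("no suitable cell in the niche/window",
                           call. = FALSE)
    if (!replace && length(idx) < n) {
      stop("fewer suitable cells (", length(idx), ") than requested records (",
           n, ") when sampling without replacement", call. = FALSE)
    }
    pick <- idx[sample.int(length(idx), n, replace = replace)]
    data.frame(species = species, lat = cc$lat[pick], lon = cc$lon[pick],
               provenance = provenance)
  })
}

#' Simulate a complete analysis world
#'
#' Generates, with one seed, every input the pipeline consumes: a mixed
#' Yule-coalescent tree with known species, a JC69 alignment on it, SST
#' raster layers, and occurrence records for `n_species` simulated taxa with
#' niche widths graded from narrow to wide (so that the qualitative
#' tolerance-vs-range relationship is built in). If `dir` is given, the
#' fixture files (newick, FASTA, occurrence CSV, three `.asc` layers) are
#' written there.
#'
#' @param n_species number of thermal-analysis species (graded niches).
#' @param k,m species and samples-per-species counts of the simulated tree.
#' @param n_records occurrence records per species.
#' @param seq_length alignment length.
#' @param seed integer seed controlling the whole world.
#' @param dir optional output directory for fixture files.
#' @return list with `tree`, `species`, `alignment`, `raster`, `occurrences`
#'   and, if `dir` was given, `paths`.
#' @export
simulate_world <- function(n_species = 8L, k = 10L, m = 5L,
                           n_records = 30L, seq_length = 500L,
                           seed = 1L, dir = NULL) {
  with_seed(seed, {
    sim <- simulate_gmyc_tree(k, m, seed = NULL)
    aln <- simulate_sequences(sim$tree, length = seq_length, seed = NULL)
    T_eq <- 28; deltaT <- 30; A0 <- 12
    raster <- simulate_sst_raster(T_eq = T_eq, deltaT = deltaT, A0 = A0,
                                  seed = NULL)
    # niche of species i = the SST envelope of a latitude band reaching to
    # lat_max[i]: tolerant species reach high latitudes (cold winters, big
    # seasonal swing), narrow ones hug the equator
    lat_max <- seq(10, 65, length.out = n_species)
    lower <- T_eq - deltaT * (lat_max / 90)^2 - A0 * lat_max / 90 - 3
    upper <- T_eq + 3
    occ <- do.call(rbind, lapply(seq_len(n_species), function(i) {
      simulate_occurrences(raster, sprintf("sim%02d", i),
                           niche = c(lower[i], upper),
                           n = n_records, seed = NULL)
    }))
    out <- list(tree = sim$tree, species = sim$species, true_N = sim$true_N,
                alignment = aln, raster = raster, occurrences = occ)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(
        tree = file.path(dir, "tree.nwk"),
        alignment = file.path(dir, "alignment.fasta"),
        occurrences = file.path(dir, "occurrences.csv"),
        sst_min = file.path(dir, "sst_min.asc"),
        sst_mean = file.path(dir, "sst_mean.asc"),
        sst_max = file.path(dir, "sst_max.asc")
      )
      writeLines(write_newick(sim$tree), paths$tree)
      write_fasta(aln, paths$alignment)
      utils::write.csv(occ, paths$occurrences, row.names = FALSE,
                       quote = FALSE)
      write_ascii_grid(raster, paths$sst_min, paths$sst_mean, paths$sst_max)
      out$paths <- paths
    }
    out
  })
}
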