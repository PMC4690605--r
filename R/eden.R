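## Stochastic Eden growth with genotypes on a hexagonal lattice.
## Layout: "pointy-top" offset rows; row r (0-based) sits at depth
## y = r * sqrt(3)/2 lattice units, odd rows shifted +1/2 laterally.
## Column 0 and column ncol-1 are blocked walls (non-periodic).  All lengths
## are in lattice units (distance between adjacent sites = 1).

ROW_DY <- sqrt(3) / 2

#' Eden simulation configuration
#'
#' Defaults mirror the study conditions: system width about 600 sites,
#' obstacle radius about 80 sites, obstacle center one third of the system
#' width ahead of the initially occupied row and laterally centered; the
#' two-obstacle variant offsets the second disk by `(5/3 R, 5/2 R)`.
#'
#' @param W system width in lattice units (occupied sites per row)
#' @param R obstacle radius in lattice units
#' @param config `"single"`, `"two-obstacle"`, or `"none"`
#' @param stop_depth run until every site up to this depth (lattice units) is
#'   occupied; default: obstacle top + 3 R (or `W` when no obstacle)
#' @param extra_rows lattice depth allocated beyond the stop row (front
#'   roughness headroom)
#' @param centers optional n x 2 matrix of obstacle centers (x, y in lattice
#'   units) overriding `config`
#' @return an object of class `fo_eden_config`
#' @export
eden_config <- function(W = 600L, R = 80L,
                        config = c("single", "two-obstacle", "none"),
                        stop_depth = NULL, extra_rows = NULL, centers = NULL) {
  config <- match.arg(config)
  W <- as.integer(W); R <- as.integer(R)
  if (W < 2 || (config != "none" && R < 2))
    fo_stop("parameter_error", "W and R must be positive lattice counts")
  if (is.null(centers)) {
    centers <- switch(config,
      none = matrix(numeric(0), 0, 2),
      single = matrix(c(W / 2, W / 3), 1, 2),
      "two-obstacle" = {
        c1 <- c(W / 2 - 5 / 6 * R, W / 3)
        rbind(c1, c1 + c(5 / 3 * R, 5 / 2 * R))
      })
  } else {
    centers <- matrix(centers, ncol = 2)
  }
  if (nrow(centers)) {
    if (any(centers[, 1] - R <= 1) || any(centers[, 1] + R >= W))
      fo_stop("invalid_geometry", "obstacle not inside lateral bounds")
    if (any(centers[, 2] - R <= ROW_DY))
      fo_stop("invalid_geometry", "obstacle overlaps the initial row")
  }
  if (is.null(stop_depth)) {
    stop_depth <- if (nrow(centers)) max(centers[, 2]) + R + 3 * R else W
  }
  stop_row <- as.integer(ceiling(stop_depth / ROW_DY))
  if (is.null(extra_rows)) extra_rows <- max(40L, ceiling(0.25 * stop_row))
  structure(list(W = W, R = R, config = config, centers = centers,
                 stop_depth = stop_depth, stop_row = stop_row,
                 n_rows = stop_row + as.integer(extra_rows) + 1L,
                 n_cols = W + 2L),
            class = "fo_eden_config")
}

# site index helpers: sites are 1-based linear indices over a row-major
# (r, c) lattice with r, c 0-based internally
site_rc <- function(idx, ncol) {
  i <- idx - 1L
  cbind(r = i %/% ncol, c = i %% ncol)
}

site_xy <- function(idx, ncol) {
  rc <- site_rc(idx, ncol)
  cbind(x = rc[, 2] + 0.5 * (rc[, 1] %% 2), y = rc[, 1] * ROW_DY)
}

eden_build_state <- function(cfg) {
  nr <- cfg$n_rows; nc <- cfg$n_cols
  st <- integer(nr * nc)
  rc <- site_rc(seq_len(nr * nc), nc)
  xy <- cbind(rc[, 2] + 0.5 * (rc[, 1] %% 2), rc[, 1] * ROW_DY)
  blocked <- rc[, 2] == 0L | rc[, 2] == nc - 1L
  if (nrow(cfg$centers)) {
    for (k in seq_len(nrow(cfg$centers))) {
      dd <- (xy[, 1] - cfg$centers[k, 1])^2 + (xy[, 2] - cfg$centers[k, 2])^2
      blocked <- blocked | dd <= cfg$R^2
    }
  }
  st[blocked] <- -1L
  init <- rc[, 1] == 0L & !blocked
  if (sum(init) != cfg$W)
    fo_stop("invalid_geometry", "obstacle overlaps the initial row")
  st[init] <- rc[init, 2]                 # genotype id = initial column 1..W
  st
}

#' Run an Eden simulation
#'
#' Repeatedly picks a uniformly random frontier site (occupied, at least one
#' empty neighbor) and copies its genotype into a uniformly random empty
#' neighbor; time advances by an exponential increment with mean
#' `1/|frontier|`.  Individuals never die.  Blocked sites (obstacle disks
#' and the lateral walls) never change state.  The run stops once every site
#' up to the configured depth is occupied.
#'
#' @param cfg an `fo_eden_config`
#' @param seed integer seed (R's RNG; identical seeds give identical runs)
#' @param max_events optional event cap (default: until the stop condition)
#' @return an object of class `fo_eden`: final `state` (genotype per site),
#'   `parent` and `btime` per site, the full event log (`ev_parent`,
#'   `ev_child`, `ev_time`, `ev_frontier_size`), the final `frontier`, and
#'   run metadata
#' @export
eden_run <- function(cfg, seed = 1L, max_events = -1L) {
  init <- eden_build_state(cfg)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  res <- eden_run_cpp(init, cfg$n_rows, cfg$n_cols, cfg$stop_row,
                      as.integer(max_events))
  if (res$status == 2L)
    fo_stop("overflow", "front reached the allocated lattice top; increase extra_rows")
  if (res$status == 1L && max_events < 0)
    fo_stop("stall", "simulation absorbed before reaching the stop depth")
  structure(c(res, list(cfg = cfg, seed = seed, init_state = init,
                        rng = "Mersenne-Twister (R set.seed)")),
            class = "fo_eden")
}

#' @export
print.fo_eden <- function(x, ...) {
  cat(sprintf("<fo_eden> W = %d, %d events, t = %.2f, %d frontier sites\n",
              x$cfg$W, x$n_events, x$final_time, length(x$frontier)))
  invisible(x)
}

#' Genotype raster of an Eden run
#' @param sim an `fo_eden`
#' @return integer matrix (rows = lattice rows from the founding row upward),
#'   `-1` blocked, `0` empty, `>0` genotype id
#' @export
eden_genotype_matrix <- function(sim) {
  t(matrix(sim$state, sim$cfg$n_cols, sim$cfg$n_rows))
}

#' Lattice coordinates of sites
#' @param sim an `fo_eden`
#' @param idx site indices
#' @return matrix with columns `x`, `y` (lattice units)
#' @export
eden_site_xy <- function(sim, idx) site_xy(idx, sim$cfg$n_cols)

#' Genealogy of frontier individuals
#'
#' Union of ancestor paths (via parent pointers) of the chosen tip sites,
#' back to the founding row.  Birth times strictly decrease along
#' child-to-parent edges.
#'
#' @param sim an `fo_eden`
#' @param tips site indices whose ancestry to reconstruct; default the final
#'   frontier
#' @return an object of class `fo_forest`: `edges` (data.frame child,
#'   parent), `tips`, `roots`, `btime` (named by site index), and per-tip
#'   root-to-tip `paths`
#' @export
genealogy <- function(sim, tips = NULL) {
  if (is.null(tips)) tips <- sim$frontier
  if (!length(tips)) fo_stop("range_error", "no tips requested")
  parent <- sim$parent
  visited <- logical(length(parent))
  children <- integer(0); parents <- integer(0)
  paths <- vector("list", length(tips))
  for (k in seq_along(tips)) {
    s <- tips[k]
    path <- s
    while (parent[s] > 0L) {
      p <- parent[s]
      if (!visited[s]) { children <- c(children, s); parents <- c(parents, p) }
      visited[s] <- TRUE
      s <- p
      path <- c(path, s)
      if (visited[s]) { # remainder already recorded; finish path via cache
        while (parent[s] > 0L) { s <- parent[s]; path <- c(path, s) }
        break
      }
    }
    visited[s] <- TRUE
    paths[[k]] <- rev(path)              # root first
  }
  roots <- unique(vapply(paths, function(p) p[1], 0L))
  structure(list(edges = data.frame(child = children, parent = parents),
                 tips = tips, roots = roots,
                 btime = sim$btime, paths = paths),
            class = "fo_forest")
}

#' Sector boundaries in a region
#'
#' All adjacent occupied site pairs with different genotype ids, grouped into
#' boundary paths (connected runs of pairs separating the same two
#' genotypes).
#'
#' @param sim an `fo_eden`
#' @param rows optional 0-based row range `c(lo, hi)` restricting the search
#' @return data.frame with site pair, genotypes, pair midpoint and `group`
#' @export
sector_boundaries <- function(sim, rows = NULL) {
  nc <- sim$cfg$n_cols; nr <- sim$cfg$n_rows
  st <- sim$state
  n <- length(st)
  rc <- site_rc(seq_len(n), nc)
  keep <- st > 0L
  if (!is.null(rows)) keep <- keep & rc[, 1] >= rows[1] & rc[, 1] <= rows[2]
  idx <- which(keep)
  pairs_a <- integer(0); pairs_b <- integer(0)
  # neighbor offsets to the "forward" half (avoid double counting):
  # right, and the two sites in the next row
  for (kind in c("right", "up1", "up2")) {
    r <- rc[idx, 1]; c <- rc[idx, 2]
    if (kind == "right") { rr <- r; cc <- c + 1L }
    else {
      off <- ifelse(r %% 2 == 0L, -1L, 0L)
      cc <- c + off + if (kind == "up1") 0L else 1L
      rr <- r + 1L
    }
    ok <- rr >= 0L & rr < nr & cc >= 0L & cc < nc
    if (!is.null(rows)) ok <- ok & rr >= rows[1] & rr <= rows[2]
    nb <- rr * nc + cc + 1L
    ok[ok] <- st[nb[ok]] > 0L
    sel <- which(ok & st[nb] != st[idx])
    pairs_a <- c(pairs_a, idx[sel]); pairs_b <- c(pairs_b, nb[sel])
  }
  if (!length(pairs_a)) {
    return(data.frame(site1 = integer(0), site2 = integer(0),
                      geno1 = integer(0), geno2 = integer(0),
                      x = numeric(0), y = numeric(0), group = integer(0)))
  }
  xy1 <- site_xy(pairs_a, nc); xy2 <- site_xy(pairs_b, nc)
  mid <- (xy1 + xy2) / 2
  g1 <- pmin(st[pairs_a], st[pairs_b]); g2 <- pmax(st[pairs_a], st[pairs_b])
  # group: same genotype pair and midpoints within 1.5 lattice units (simple
  # single-linkage chaining per genotype pair)
  group <- integer(length(pairs_a))
  gid <- 0L
  for (key in unique(paste(g1, g2))) {
    sel <- which(paste(g1, g2) == key)
    ord <- sel[order(mid[sel, 2], mid[sel, 1])]
    for (i in seq_along(ord)) {
      if (i == 1) { gid <- gid + 1L; group[ord[i]] <- gid; next }
      prev <- ord[seq_len(i - 1)]
      near <- prev[(mid[prev, 1] - mid[ord[i], 1])^2 +
                   (mid[prev, 2] - mid[ord[i], 2])^2 <= 2.25]
      if (length(near)) group[ord[i]] <- group[near[length(near)]]
      else { gid <- gid + 1L; group[ord[i]] <- gid }
    }
  }
  data.frame(site1 = pairs_a, site2 = pairs_b, geno1 = g1, geno2 = g2,
             x = mid[, 1], y = mid[, 2], group = group)
}

# walk a site's ancestry until reaching the lattice row nearest target_row;
# returns the x coordinate there (NA if never visited)
ancestor_x_at_row <- function(sim, site, target_row) {
  nc <- sim$cfg$n_cols
  parent <- sim$parent
  s <- site
  repeat {
    rc <- site_rc(s, nc)
    if (rc[1] == target_row) return(site_xy(s, nc)[1])
    if (parent[s] <= 0L) return(NA_real_)
    s <- parent[s]
  }
}

#' Detect a sector boundary pinned at an obstacle top
#'
#' Looks for a genotype boundary within `window_frac * R` laterally of the
#' obstacle's vertical symmetry axis in the first `R/4` depth units beyond
#' its top, whose two flanking sectors trace (via parent pointers) to sites
#' on opposite lateral sides of the obstacle at its max-width row.
#'
#' @param sim an `fo_eden`
#' @param obstacle obstacle index into the config's centers
#' @param window_frac lateral search half-window as a fraction of R
#' @return list with `pinned` (logical), and when found `x`, `y`, `genotypes`
#' @export
detect_pinned_boundary <- function(sim, obstacle = 1L, window_frac = 1 / 8) {
  cfg <- sim$cfg
  if (!nrow(cfg$centers)) fo_stop("not_applicable", "run has no obstacle")
  ctr <- cfg$centers[obstacle, ]
  R <- cfg$R
  top_y <- ctr[2] + R
  row_lo <- ceiling(top_y / ROW_DY)
  row_hi <- ceiling((top_y + R / 4) / ROW_DY)
  # readiness: the front must have passed the inspection band
  rc_all <- site_rc(seq_along(sim$state), cfg$n_cols)
  band <- rc_all[, 1] <= row_hi & rc_all[, 1] >= row_lo
  if (any(sim$state[band] == 0L))
    fo_stop("not_ready", "front has not fully passed the obstacle top")
  sb <- sector_boundaries(sim, rows = c(row_lo, row_hi))
  if (nrow(sb)) {
    sb <- sb[abs(sb$x - ctr[1]) <= window_frac * R, , drop = FALSE]
    row_mw <- round(ctr[2] / ROW_DY)
    for (i in seq_len(nrow(sb))) {
      x1 <- ancestor_x_at_row(sim, sb$site1[i], row_mw)
      x2 <- ancestor_x_at_row(sim, sb$site2[i], row_mw)
      if (!is.na(x1) && !is.na(x2) &&
          sign(x1 - ctr[1]) * sign(x2 - ctr[1]) < 0) {
        return(list(pinned = TRUE, x = sb$x[i], y = sb$y[i],
                    genotypes = c(sb$geno1[i], sb$geno2[i])))
      }
    }
  }
  list(pinned = FALSE)
}

#' Classify lineage routes around obstacles
#'
#' For each root-to-tip path of the forest, records on which side of each
#' obstacle it passes (lateral position at the row of the obstacle's maximal
#' width) and whether it grazes the obstacle (comes within `graze_dist`
#' lattice units of the disk boundary).
#'
#' @param sim an `fo_eden`
#' @param forest an `fo_forest` (default: genealogy of the final frontier)
#' @param graze_dist graze threshold (lattice units)
#' @return data.frame with columns `tip`, `obstacle`, `side`
#'   (`"left"`/`"right"`), `graze` (logical)
#' @export
classify_lineage_route <- function(sim, forest = NULL, graze_dist = 2) {
  cfg <- sim$cfg
  if (is.null(forest)) forest <- genealogy(sim)
  if (!nrow(cfg$centers))
    return(data.frame(tip = integer(0), obstacle = integer(0),
                      side = character(0), graze = logical(0)))
  out <- list()
  for (k in seq_along(forest$paths)) {
    path <- forest$paths[[k]]
    xy <- site_xy(path, cfg$n_cols)
    for (ob in seq_len(nrow(cfg$centers))) {
      ctr <- cfg$centers[ob, ]
      dd <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
      if (any(dd < cfg$R - 0.5))
        fo_stop("internal_consistency", "lineage passes through obstacle interior")
      near_row <- which.min(abs(xy[, 2] - ctr[2]))
      side <- if (xy[near_row, 1] < ctr[1]) "left" else "right"
      graze <- any(dd <= cfg$R + graze_dist)
      out[[length(out) + 1L]] <- data.frame(
        tip = forest$tips[k], obstacle = ob, side = side, graze = graze)
    }
  }
  do.call(rbind, out)
}

#' Replay an event log
#'
#' Rebuilds lattice states from the initial condition and the event log.
#' Used as an independent check of the incremental bookkeeping and to sample
#' frontier composition over time.
#'
#' @param sim an `fo_eden`
#' @param at_events event counts at which to snapshot (default: final only)
#' @return list of snapshots, each with `state`, `parent`, `n_events`,
#'   `frontier` (recomputed from scratch), `frontier_genotypes`
#' @export
eden_replay <- function(sim, at_events = NULL) {
  cfg <- sim$cfg
  nc <- cfg$n_cols; nr <- cfg$n_rows
  if (is.null(at_events)) at_events <- sim$n_events
  at_events <- sort(unique(pmin(at_events, sim$n_events)))
  st <- sim$init_state
  parent <- integer(length(st))
  snaps <- vector("list", length(at_events))
  done <- 0L
  frontier_of <- function(st) {
    occ <- which(st > 0L)
    rc <- site_rc(occ, nc)
    has_empty <- logical(length(occ))
    for (kind in 1:6) {
      r <- rc[, 1]; c <- rc[, 2]
      off <- ifelse(r %% 2 == 0L, -1L, 0L)
      rr <- switch(kind, r, r, r - 1L, r - 1L, r + 1L, r + 1L)
      cc <- switch(kind, c - 1L, c + 1L, c + off, c + off + 1L,
                   c + off, c + off + 1L)
      ok <- rr >= 0L & rr < nr & cc >= 0L & cc < nc
      nb <- rr * nc + cc + 1L
      emp <- ok
      emp[ok] <- st[nb[ok]] == 0L
      has_empty <- has_empty | emp
    }
    occ[has_empty]
  }
  for (si in seq_along(at_events)) {
    upto <- at_events[si]
    if (upto > done) {
      # strictly sequential: a child in this range may itself become a parent
      for (e in (done + 1L):upto) {
        st[sim$ev_child[e]] <- st[sim$ev_parent[e]]
        parent[sim$ev_child[e]] <- sim$ev_parent[e]
      }
      done <- upto
    }
    fr <- frontier_of(st)
    snaps[[si]] <- list(state = st, parent = parent, n_events = upto,
                        frontier = fr,
                        frontier_genotypes = unique(st[fr]))
  }
  snaps
}

#' Export a lineage forest as Newick trees
#'
#' One Newick string per root; branch lengths are birth-time differences
#' between child and parent.  Tip/internal labels are `s<site index>`.
#'
#' @param forest an `fo_forest`
#' @return character vector of Newick strings
#' @export
lineage_newick <- function(forest) {
  if (!nrow(forest$edges)) {
    return(sprintf("s%d;", forest$tips))
  }
  kids <- split(forest$edges$child, forest$edges$parent)
  bt <- forest$btime
  vapply(forest$roots, function(root) {
    # iterative post-order construction
    build <- function(node) {
      stack <- list(list(node = node, stage = 1L))
      outs <- list()
      while (length(stack)) {
        fr <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        ch <- kids[[as.character(fr$node)]]
        if (fr$stage == 1L && length(ch)) {
          stack[[length(stack) + 1L]] <- list(node = fr$node, stage = 2L)
          for (c2 in ch) stack[[length(stack) + 1L]] <- list(node = c2, stage = 1L)
        } else {
          bl <- if (fr$node == root) 0 else bt[fr$node] - bt[forest$edges$parent[match(fr$node, forest$edges$child)]]
          lab <- sprintf("s%d:%.6g", fr$node, bl)
          if (fr$stage == 2L) {
            nch <- length(ch)
            sub <- outs[seq(length(outs) - nch + 1L, length(outs))]
            outs <- outs[seq_len(length(outs) - nch)]
            outs[[length(outs) + 1L]] <- sprintf("(%s)%s",
              paste(rev(unlist(sub)), collapse = ","), lab)
          } else {
            outs[[length(outs) + 1L]] <- lab
          }
        }
      }
      outs[[1]]
    }
    paste0(build(root), ";")
  }, "")
}
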