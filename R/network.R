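#' Sample heterogeneous parameter values
#'
#' Draws per-cell (or per-connection) values from a normal distribution whose
#' SD is a fixed fraction of the mean, the scheme used for all neuron,
#' synapse and astrocyte parameters in the network.
#'
#' @param mean base (mean) value; may be a vector.
#' @param n number of draws (ignored when `mean` is a vector of the target
#'   length).
#' @param sd_frac SD as a fraction of `|mean|` (default 1\%).
#' @return numeric vector of draws.
#' @export
sample_heterogeneity <- function(mean, n = length(mean), sd_frac = 0.01) {
  rnorm(n, mean = mean, sd = sd_frac * abs(mean))
}

window_neighbors <- function(rows, cols, half, exclude_self = TRUE) {
  # neighbor site indices (row-major, 1-based) within a Chebyshev radius,
  # truncated at the grid edge
  n <- rows * cols
  r <- ((seq_len(n) - 1L) %/% cols) + 1L
  c <- ((seq_len(n) - 1L) %% cols) + 1L
  lapply(seq_len(n), function(i) {
    rr <- max(1L, r[i] - half):min(rows, r[i] + half)
    cc <- max(1L, c[i] - half):min(cols, c[i] + half)
    idx <- as.integer(outer((rr - 1L) * cols, cc, "+"))
    if (exclude_self) idx <- idx[idx != i]
    sort(idx)
  })
}

#' Build the neuron-astrocyte network
#'
#' Lays out neurons on a 2D grid (default 20x20 = 320 excitatory + 80
#' inhibitory, randomly placed), defines the stimulation focus as the centered
#' square block (default 7x7, 49 sites), builds windowed connectivity
#' (excitatory inputs from the excitatory neurons in each cell's 7x7
#' neighborhood, at most 48; inhibitory inputs from the inhibitory neurons in
#' the 3x3 neighborhood, at most 8; windows truncated at the edges, no
#' self-connections) and tiles one astrocyte per site (1:1 with neurons).
#' Each astrocyte integrates spikes of the excitatory neurons in its 3x3
#' territory and feeds back onto the neurons of that same territory.
#' All per-cell and per-connection parameters are drawn with
#' [sample_heterogeneity()]; the build is deterministic given `seed`.
#'
#' @param config a [sim_config()] (only the structural and parameter fields
#'   are used).
#' @param seed RNG seed for placement and parameter draws.
#' @return list of class `"ictal_network"` with elements `layout`
#'   (grid_shape, cell_class, is_exc, focus_mask, n), `conn` (per-neuron
#'   input index lists and weight lists), `tiling` (per-astrocyte patch,
#'   sigma weights, targets, alpha, beta), and `het` (per-neuron a, b, c, d).
#' @export
build_network <- function(config = sim_config(), seed = config$seed) {
  rows <- config$grid[1]; cols <- config$grid[2]
  n <- rows * cols
  if (config$n_exc + config$n_inh != n)
    stop("n_exc + n_inh must equal the grid area")
  if (config$focus_size > min(rows, cols) ||
      config$exc_window > 2 * min(rows, cols) - 1)
    stop("grid smaller than the connectivity/focus windows")
  set.seed(seed)

  # --- placement -----------------------------------------------------------
  is_exc <- logical(n)
  is_exc[sample.int(n, config$n_exc)] <- TRUE

  # centered focus block
  half_lo <- (c(rows, cols) - config$focus_size) %/% 2
  r <- ((seq_len(n) - 1L) %/% cols) + 1L
  c <- ((seq_len(n) - 1L) %% cols) + 1L
  focus_mask <- r > half_lo[1] & r <= half_lo[1] + config$focus_size &
    c > half_lo[2] & c <= half_lo[2] + config$focus_size

  # --- per-neuron Izhikevich parameters ------------------------------------
  pe <- config$neuron_exc; pi <- config$neuron_inh
  sd <- config$sd_frac
  a <- b <- cc <- d <- numeric(n)
  ne <- sum(is_exc); ni <- n - ne
  a[is_exc] <- sample_heterogeneity(pe$a, ne, sd)
  b[is_exc] <- sample_heterogeneity(pe$b, ne, sd)
  cc[is_exc] <- sample_heterogeneity(pe$c, ne, sd)
  d[is_exc] <- sample_heterogeneity(pe$d, ne, sd)
  a[!is_exc] <- sample_heterogeneity(pi$a, ni, sd)
  b[!is_exc] <- sample_heterogeneity(pi$b, ni, sd)
  cc[!is_exc] <- sample_heterogeneity(pi$c, ni, sd)
  d[!is_exc] <- sample_heterogeneity(pi$d, ni, sd)
  # truncate b draws so every cell keeps a resting fixed point at its holding
  # current (the inhibitory default sits ~3 SD below the saddle-node); keeps
  # the unstimulated network strictly silent
  hold <- ifelse(is_exc, config$tonic_current, 0)
  b_max <- 5 - sqrt(4 * 0.04 * (140 + hold)) - 1e-4
  b <- pmin(b, b_max)

  # --- connectivity --------------------------------------------------------
  exc_half <- (config$exc_window - 1L) %/% 2L
  inh_half <- (config$inh_window - 1L) %/% 2L
  wide <- window_neighbors(rows, cols, exc_half, exclude_self = TRUE)
  narrow <- window_neighbors(rows, cols, inh_half, exclude_self = TRUE)
  exc_inputs <- lapply(wide, function(idx) idx[is_exc[idx]])
  inh_inputs <- lapply(narrow, function(idx) idx[!is_exc[idx]])
  sp <- config$synapse
  exc_w <- lapply(exc_inputs, function(idx)
    sample_heterogeneity(sp$s_exc, length(idx), sd))
  inh_w <- lapply(inh_inputs, function(idx)
    sample_heterogeneity(sp$s_inh, length(idx), sd))

  # --- astrocyte tiling ----------------------------------------------------
  astro_half <- (config$astro_window - 1L) %/% 2L
  terr <- window_neighbors(rows, cols, astro_half, exclude_self = FALSE)
  ap <- config$astro_params
  patch <- lapply(terr, function(idx) idx[is_exc[idx]])
  sigma_w <- lapply(patch, function(idx)
    sample_heterogeneity(ap$sigma, length(idx), sd))
  targets <- if (config$astro_targets_exc_only) patch else terr
  alpha <- sample_heterogeneity(ap$alpha, n, sd)
  beta <- sample_heterogeneity(ap$beta, n, sd)

  structure(list(
    layout = list(grid_shape = c(rows, cols), n = n, is_exc = is_exc,
                  cell_class = ifelse(is_exc, "excitatory", "inhibitory"),
                  focus_mask = focus_mask, row = r, col = c),
    conn = list(exc_inputs = exc_inputs, exc_w = exc_w,
                inh_inputs = inh_inputs, inh_w = inh_w),
    tiling = list(patch = patch, sigma = sigma_w, targets = targets,
                  alpha = alpha, beta = beta),
    het = list(a = a, b = b, c = cc, d = d),
    seed = seed
  ), class = "ictal_network")
}

#' Export connectivity as an edge list
#'
#' @param network an [build_network()] result.
#' @return data.frame with columns `pre`, `post`, `type`
#'   (`"exc"`, `"inh"`, `"astro"`), `weight`.
#' @export
edge_list <- function(network) {
  conn <- network$conn; til <- network$tiling
  post_e <- rep(seq_along(conn$exc_inputs), lengths(conn$exc_inputs))
  post_i <- rep(seq_along(conn$inh_inputs), lengths(conn$inh_inputs))
  post_a <- rep(seq_along(til$targets), lengths(til$targets))
  data.frame(
    pre = c(unlist(conn$exc_inputs), unlist(conn$inh_inputs),
            rep(seq_along(til$targets), lengths(til$targets))),
    post = c(post_e, post_i, unlist(til$targets)),
    type = rep(c("exc", "inh", "astro"),
               c(length(post_e), length(post_i), length(post_a))),
    weight = c(unlist(conn$exc_w), unlist(conn$inh_w),
               rep(1, length(post_a)))
  )
}
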