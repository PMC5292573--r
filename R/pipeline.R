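#' Run the filter -> connectivity -> graph pipeline on one recording
#'
#' Batch orchestration of the analysis stages on a single window of
#' multichannel data: optional zero-phase band-pass filtering, one or
#' more connectivity indices, PLV significance with FDR correction, and
#' optional graph metrics on the PLV matrix.  Every parameter is
#' validated against the owning stage's preconditions before any
#' computation starts, outputs are named deterministically from
#' `out_prefix`, and partially written files are removed if a stage
#' fails, so a run directory never holds output from a failed run.
#'
#' @param config named list with entries:
#' \describe{
#'   \item{input / data}{path of a delimited text matrix, or a
#'     `signal_matrix` directly (exactly one required).}
#'   \item{out_prefix}{prefix (possibly with directory) for all output
#'     files.}
#'   \item{fs}{sampling rate in Hz (required with `band` or spectral
#'     indices).}
#'   \item{band, order}{pass band `c(low, high)` in Hz and FIR order for
#'     the filtering stage; omit `band` to skip filtering.}
#'   \item{discard}{border samples excluded from phase averages
#'     (default 0).}
#'   \item{indices}{character subset of `"plv"`, `"pli"`, `"imc"`,
#'     `"wpli"`, `"mi"`, `"gs"` (default `"plv"`).}
#'   \item{q}{FDR level for PLV discoveries (default 0.05).}
#'   \item{segments}{Welch segment count for imc/wpli (default 5).}
#'   \item{mi_k, mi_normalization}{mutual-information parameters.}
#'   \item{gs_m, gs_tau, gs_k, gs_theiler, gs_stride}{embedding
#'     parameters; `gs_m` and `gs_tau` are required when `"gs"` is
#'     requested.}
#'   \item{graph}{if `TRUE`, compute strength, clustering, path length
#'     and betweenness on the PLV matrix (diagonal zeroed).}
#'   \item{labels, transpose, seed, verbose}{I/O and reproducibility
#'     switches (seed feeds the MI jitter; default 1).}
#' }
#' @return Invisibly, a list with `files` (paths written) and `config`
#'   (the validated configuration, the full parameter log of the run).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  get_or <- function(name, default) if (is.null(cfg[[name]])) default else cfg[[name]]
  indices <- get_or("indices", "plv")
  known <- c("plv", "pli", "imc", "wpli", "mi", "gs")
  if (!all(indices %in% known))
    fcnet_stop(sprintf("unknown index: %s",
                       paste(setdiff(indices, known), collapse = ", ")),
               "fcnet_param")
  if (is.null(cfg$out_prefix))
    fcnet_stop("out_prefix is required", "fcnet_param")
  if ("gs" %in% indices && (is.null(cfg$gs_m) || is.null(cfg$gs_tau)))
    fcnet_stop("gs requires gs_m and gs_tau", "fcnet_param")
  if (!is.null(cfg$band) && is.null(cfg$fs) &&
      !(inherits(cfg$data, "signal_matrix") && !is.null(cfg$data$fs)))
    fcnet_stop("filtering requires fs", "fcnet_param")

  sm <- if (!is.null(cfg$data)) as_signal_matrix(cfg$data)
        else if (!is.null(cfg$input))
          read_signal_matrix(cfg$input, labels = isTRUE(cfg$labels),
                             fs = cfg$fs, transpose = isTRUE(cfg$transpose))
        else fcnet_stop("config needs input (path) or data (signal_matrix)",
                        "fcnet_param")
  if (!is.null(cfg$fs)) sm$fs <- cfg$fs
  discard <- get_or("discard", 0)
  seed <- get_or("seed", 1)
  verbose <- isTRUE(cfg$verbose)
  say <- function(...) if (verbose) message(sprintf(...))

  # validate filter parameters before touching any file
  kernel <- NULL
  if (!is.null(cfg$band)) {
    kernel <- design_windowed_sinc(get_or("order", 200), cfg$band, sm$fs)
    if (length(kernel) >= ncol(sm$data))
      fcnet_stop("filter order too high for the signal length",
                 "fcnet_kernel_too_long")
  }

  files <- character(0)
  out <- function(suffix) paste0(cfg$out_prefix, ".", suffix)
  emit <- function(values, suffix, labels = NULL) {
    path <- out(suffix)
    write_matrix(values, path, labels = labels)
    files <<- c(files, path)
    path
  }

  tryCatch({
    work <- sm
    if (!is.null(kernel)) {
      say("filtering %d channel(s), band [%g, %g] Hz", nrow(sm$data),
          cfg$band[1], cfg$band[2])
      work <- filtfilt_fft(sm, kernel)
      emit(work, "filtered.tsv")
    }
    plv_mat <- NULL
    if (any(c("plv", "pli") %in% indices)) {
      ph <- instantaneous_phase(analytic_signal(work), discard = discard)
      n_eff <- ncol(work$data) - 2 * discard
      if ("plv" %in% indices) {
        say("phase locking value (%d effective samples)", n_eff)
        plv_mat <- plv(ph)
        emit(plv_mat, "plv.tsv")
        pv <- bh_fdr(plv_significance(plv_mat, n_eff), get_or("q", 0.05))
        emit(pv$p, "plv.pvals.tsv", labels = work$labels)
        emit(pv$fdr_mask + 0, "plv.fdr_mask.tsv", labels = work$labels)
      }
      if ("pli" %in% indices) emit(pli(ph), "pli.tsv")
    }
    if (any(c("imc", "wpli") %in% indices)) {
      cs <- welch_cross_spectra(work, n_segments = get_or("segments", 5))
      band <- get_or("band", range(cs$freqs))
      if ("imc" %in% indices) emit(imc(cs, band), "imc.tsv")
      if ("wpli" %in% indices) emit(wpli(cs, band), "wpli.tsv")
    }
    if ("mi" %in% indices) {
      say("mutual information, k = %d", get_or("mi_k", 4))
      mi <- mi_matrix(work, k = get_or("mi_k", 4),
                      normalization = get_or("mi_normalization", "none"),
                      seed = seed)
      emit(mi$mi, "mi.tsv")
      emit(mi$entropies, "mi.entropy.tsv", labels = work$labels)
    }
    if ("gs" %in% indices) {
      say("generalized synchronization, m = %d, tau = %d",
          cfg$gs_m, cfg$gs_tau)
      gs <- gs_matrix(work, m = cfg$gs_m, tau = cfg$gs_tau,
                      k = get_or("gs_k", 4), theiler = cfg$gs_theiler,
                      stride = get_or("gs_stride", 1))
      for (nm in c("S", "H", "M", "L"))
        emit(gs[[nm]], sprintf("gs_%s.tsv", tolower(nm)))
    }
    if (isTRUE(cfg$graph)) {
      if (is.null(plv_mat))
        fcnet_stop("graph metrics require the plv index", "fcnet_param")
      W <- unclass(plv_mat)
      diag(W) <- 0
      say("graph metrics on the PLV network (%d nodes)", nrow(W))
      emit(node_strength(W), "strength.tsv")
      emit(weighted_clustering(W)$nodal, "clustering.tsv")
      bc <- betweenness_centrality(W)
      cp <- char_path_length(bc$distances)
      emit(cp$nodal, "pathlength.tsv", labels = work$labels)
      emit(bc$betweenness, "betweenness.tsv")
      emit(bc$distances, "dist.tsv")
    }
    invisible(list(files = files, config = cfg))
  }, error = function(e) {
    unlink(files)
    stop(e)
  })
}
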