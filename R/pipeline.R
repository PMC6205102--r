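pipeline_defaults <- function() {
  list(
    inputs = NULL,            # list of input entries (see validate_input)
    exclude_channels = list(),
    bands = NULL,             # NULL -> standard_bands()
    window_s = 1,
    overlap = 0.5,
    edge_margin_s = 0.25,
    filter = list(method = "onepass", transition_hz = NULL),
    clustering = list(k_min = 2, k_max = 20, band = "broadband"),
    stats = list(p_adjust = "bonferroni"),
    write_connectivity = FALSE,
    output_dir = NULL
  )
}

validate_config <- function(config) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  for (nm in c("filter", "clustering", "stats")) {
    bad <- setdiff(names(cfg[[nm]]), names(defaults[[nm]]))
    if (length(bad) > 0) {
      stop("unknown config key(s) under '", nm, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(cfg$output_dir)) stop("config needs `output_dir`", call. = FALSE)
  if (is.null(cfg$inputs) || length(cfg$inputs) == 0) {
    stop("config needs at least one entry under `inputs`", call. = FALSE)
  }
  if (!is.null(names(cfg$inputs)) && any(names(cfg$inputs) != "")) {
    cfg$inputs <- list(cfg$inputs)  # single unnamed-list input entry
  }
  cfg$bands <- resolve_bands(cfg$bands)
  # validate band edges against each input's sampling rate before any work
  for (inp in cfg$inputs) {
    fs <- input_fs(inp)
    if (!is.null(fs)) {
      for (b in cfg$bands) {
        if (b$name != "broadband" && b$high_hz >= fs / 2) {
          stop("band '", b$name, "' upper edge ", b$high_hz,
               " Hz reaches Nyquist for fs = ", fs, " Hz", call. = FALSE)
        }
      }
    }
  }
  cfg
}

resolve_bands <- function(bands) {
  if (is.null(bands)) return(standard_bands())
  out <- lapply(bands, function(b) {
    if (inherits(b, "band_spec")) b
    else band_spec(b$name, b$low_hz %||% NULL, b$high_hz %||% NULL)
  })
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

input_fs <- function(inp) {
  if (isTRUE(inp$synthetic)) return(inp$fs %||% 500)
  if (!is.null(inp$fs)) return(inp$fs)
  sidecar <- paste0(inp$path, ".yaml")
  if (!is.null(inp$path) && file.exists(sidecar)) {
    return(yaml::read_yaml(sidecar)$fs)
  }
  NULL
}

load_input <- function(inp) {
  allowed <- c("path", "format", "fs", "onset_s", "termination_s",
               "channel_labels", "synthetic", "M", "seizure_s", "switch_s",
               "seed", "name")
  unknown <- setdiff(names(inp), allowed)
  if (length(unknown) > 0) {
    stop("unknown input key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (isTRUE(inp$synthetic)) {
    sim <- make_seizure_fixture(M = inp$M %||% 48, fs = inp$fs %||% 500,
                                seizure_s = inp$seizure_s %||% 60,
                                switch_s = inp$switch_s %||% 10,
                                seed = inp$seed %||% 1)
    return(sim$recording)
  }
  if (is.null(inp$path)) stop("input needs `path` or `synthetic: true`",
                              call. = FALSE)
  read_recording(inp$path, format = inp$format %||% "auto",
                 fs = inp$fs, onset_s = inp$onset_s,
                 termination_s = inp$termination_s,
                 channel_labels = inp$channel_labels)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full peri-seizure network pipeline
#'
#' Orchestrates, for every input recording and every configured band:
#' band extraction, instantaneous phase, sliding-window mean-phase-coherence
#' connectivity, degree vectors and mean phase synchronization, per-period
#' summaries, Ward clustering into network states with automatic selection of
#' the state count, and state-change rates. When two or more inputs (seizures)
#' are configured, the Friedman test with Dunn's post hoc comparisons is run
#' across periods on the per-seizure summaries. All artifacts are tidy CSV
#' files under `output_dir`, plus a JSON run manifest recording the package
#' version, the resolved configuration and its MD5 hash; outputs are
#' byte-identical across runs with the same configuration.
#'
#' @param config a named list, or the path to a YAML file holding one. Keys
#'   (unknown keys are rejected): `inputs` (list of entries, each either
#'   `path`/`format`/`fs`/`onset_s`/`termination_s`/`channel_labels` for a
#'   file or `synthetic: true` with `M`, `fs`, `seizure_s`, `switch_s`,
#'   `seed`), `exclude_channels`, `bands` (name/low_hz/high_hz entries;
#'   default broadband + theta/alpha/beta/gamma), `window_s`, `overlap`,
#'   `edge_margin_s`, `filter` (`method`, `transition_hz`), `clustering`
#'   (`k_min`, `k_max`, `band`), `stats` (`p_adjust`), `write_connectivity`,
#'   `output_dir`.
#' @return the output directory, invisibly; side effect: files written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- stage("config", validate_config(config))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  all_summaries <- list()
  all_rates <- list()
  for (s in seq_along(cfg$inputs)) {
    inp <- cfg$inputs[[s]]
    id <- inp$name %||% sprintf("seizure%02d", s)
    rec <- stage("read", load_input(inp))
    rec <- stage("bad_channels",
                 remove_bad_channels(rec, unlist(cfg$exclude_channels)))
    seg <- stage("segmentation", segment_periods(rec))
    span <- rec  # analysis span: preseizure_full .. postseizure_full
    iv <- c(period_interval(seg, "preseizure_full")[1],
            period_interval(seg, "postseizure_full")[2])
    span <- stage("segmentation", crop_recording(rec, iv[1], iv[2]))
    span$onset_s <- rec$onset_s; span$termination_s <- rec$termination_s
    for (band in cfg$bands) {
      tag <- paste0(id, "_", band$name)
      filtered <- stage("bandpass",
                        bandpass_filter(span, band,
                                        method = cfg$filter$method,
                                        transition_hz = cfg$filter$transition_hz))
      ph <- stage("phase", analytic_phase(filtered, cfg$edge_margin_s))
      conn <- stage("connectivity",
                    sliding_connectivity(ph, window_s = cfg$window_s,
                                         overlap = cfg$overlap))
      deg <- stage("network", degree_vectors(conn))
      mps <- stage("network", mean_phase_synchronization(deg))
      summ <- stage("network", summarize_periods(mps, seg))
      if (cfg$write_connectivity) {
        stage("export", write_csv(connectivity_long(conn),
                                  file.path(cfg$output_dir,
                                            paste0("connectivity_", tag,
                                                   ".csv"))))
      }
      stage("export", {
        dd <- data.frame(window_center_s = rep(deg$window_centers_s,
                                               ncol(deg$degrees)),
                         channel = rep(deg$channel_labels,
                                       each = nrow(deg$degrees)),
                         degree = as.vector(deg$degrees))
        write_csv(dd, file.path(cfg$output_dir,
                                paste0("degree_", tag, ".csv")))
        write_csv(as.data.frame(mps),
                  file.path(cfg$output_dir, paste0("mean_ps_", tag, ".csv")))
      })
      all_summaries[[tag]] <- cbind(seizure = id, band = band$name,
                                    as.data.frame(summ))
      link <- stage("states", ward_linkage(deg))
      w <- nrow(link$data)
      k <- stage("states",
                 select_k(link, k_min = min(cfg$clustering$k_min, w - 2),
                          k_max = min(cfg$clustering$k_max, w - 2)))
      st <- stage("states", assign_states(link, k))
      rates <- stage("states", state_change_rate(st, seg))
      stage("export", {
        write_csv(data.frame(window_center_s = st$window_centers_s,
                             state = st$labels),
                  file.path(cfg$output_dir, paste0("states_", tag, ".csv")))
        write_csv(data.frame(left = link$merge[, 1], right = link$merge[, 2],
                             distance = link$height,
                             size = merge_sizes(link$merge)),
                  file.path(cfg$output_dir, paste0("linkage_", tag, ".csv")))
        write_csv(as.data.frame(rates),
                  file.path(cfg$output_dir, paste0("rates_", tag, ".csv")))
      })
      all_rates[[tag]] <- cbind(seizure = id, band = band$name,
                                as.data.frame(rates))
    }
  }
  summaries <- do.call(rbind, all_summaries)
  rates_df <- do.call(rbind, all_rates)
  write_csv(summaries, file.path(cfg$output_dir, "period_summary.csv"))
  write_csv(rates_df, file.path(cfg$output_dir, "state_change_rates.csv"))
  if (length(cfg$inputs) >= 2) {
    stage("group_stats",
          run_group_stats(summaries, rates_df, cfg))
  }
  stage("manifest", write_manifest(cfg))
  invisible(cfg$output_dir)
}

connectivity_long <- function(conn) {
  m <- dim(conn$matrices)[1]
  ut <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  do.call(rbind, lapply(seq_len(dim(conn$matrices)[3]), function(w) {
    data.frame(window_center_s = conn$window_centers_s[w],
               from = conn$channel_labels[ut[, 1]],
               to = conn$channel_labels[ut[, 2]],
               lambda = conn$matrices[, , w][ut])
  }))
}

merge_sizes <- function(merge) {
  sz <- integer(nrow(merge))
  for (i in seq_len(nrow(merge))) {
    sz[i] <- sum(ifelse(merge[i, ] < 0, 1, sz[pmax(merge[i, ], 1)]))
  }
  sz
}

run_group_stats <- function(summaries, rates_df, cfg) {
  stage_periods <- c("preS", "S1", "S2", "S3", "S4", "postS")
  for (band in names(cfg$bands)) {
    sub <- summaries[summaries$band == band, ]
    tab <- stats::reshape(sub[, c("seizure", "period", "mean_ps")],
                          idvar = "seizure", timevar = "period",
                          direction = "wide")
    mat <- as.matrix(tab[, -1])
    colnames(mat) <- sub("^mean_ps\\.", "", colnames(mat))
    mat <- mat[, stage_periods, drop = FALSE]
    res <- dunn_posthoc(mat, p_adjust = cfg$stats$p_adjust)
    write_csv(as.data.frame(res),
              file.path(cfg$output_dir, paste0("stats_mean_ps_", band,
                                               ".csv")))
    txt <- file.path(cfg$output_dir, paste0("stats_mean_ps_", band, ".txt"))
    con <- file(txt, "w"); sink(con); print(res); sink(); close(con)
  }
  # state-change rates across the three equal-length periods
  tab <- stats::reshape(rates_df[rates_df$band == cfg$clustering$band,
                                 c("seizure", "period", "rate_per_s")],
                        idvar = "seizure", timevar = "period",
                        direction = "wide")
  mat <- as.matrix(tab[, -1])
  colnames(mat) <- sub("^rate_per_s\\.", "", colnames(mat))
  res <- dunn_posthoc(mat, p_adjust = cfg$stats$p_adjust)
  write_csv(as.data.frame(res),
            file.path(cfg$output_dir, "stats_change_rate.csv"))
  invisible(NULL)
}

write_manifest <- function(cfg) {
  cfg_for_hash <- cfg
  cfg_for_hash$bands <- lapply(cfg$bands, unclass)
  tmp <- file.path(cfg$output_dir, "config_resolved.yaml")
  yaml::write_yaml(cfg_for_hash, tmp)
  manifest <- list(
    package = "phasenet",
    version = as.character(utils::packageVersion("phasenet")),
    config_md5 = unname(tools::md5sum(tmp)),
    config = cfg_for_hash
  )
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(NULL)
}

#' Generate and write a synthetic fixture from a config
#'
#' Thin wrapper over [make_seizure_fixture()] + [write_fixture()]: validates
#' the request and writes the recording (plain matrix + YAML sidecar) and the
#' JSON ground truth into `output_dir`.
#'
#' @param config named list (or YAML path) with keys `M` (>= 2), `fs`,
#'   `seizure_s`, `switch_s`, `seed`, `output_dir`, `name`.
#' @return named vector of written files, invisibly.
#' @export
simulate_command <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  allowed <- c("M", "fs", "seizure_s", "switch_s", "seed", "output_dir",
               "name")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$output_dir)) stop("config needs `output_dir`",
                                       call. = FALSE)
  m <- config$M %||% 48
  if (m < 2) stop("connectivity needs M >= 2 channels", call. = FALSE)
  sim <- make_seizure_fixture(M = m, fs = config$fs %||% 500,
                              seizure_s = config$seizure_s %||% 60,
                              switch_s = config$switch_s %||% 10,
                              seed = config$seed %||% 1)
  write_fixture(sim, config$output_dir, config$name %||% "recording")
}
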