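# End-to-end pipeline: build -> dock -> select top pose -> synthetic
# bound-complex trajectory (standing in for the atomistic refinement
# stage, which is far beyond desk scale) -> analysis -> report bundle.

#' Parse a flat key-value config file
#'
#' Minimal YAML-dialect: one `key: value` pair per line, `#` comments,
#' comma-separated values become vectors, numbers are coerced.
#'
#' @param path config file
#' @return named list
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("bad config line: ", ln)
    vals <- trimws(strsplit(m[3], ",")[[1]])
    num <- suppressWarnings(as.numeric(vals))
    out[[m[2]]] <- if (!anyNA(num)) num else vals
  }
  out
}

#' Pipeline configuration
#'
#' Desk-scale defaults: the docking stage is scaled down (tens of short
#' runs rather than 5000 x 500 ns) so the full pipeline completes in
#' minutes on one CPU; all physical parameters keep their standard
#' values.
#'
#' @param seed base seed propagated to every stochastic stage
#' @param out_dir output directory
#' @param peptide_sequence one-letter sequence
#' @param n_runs,run_length docking scale (runs, ns per run)
#' @param n_record pose store size
#' @param contact_cutoff ligand-contact cutoff, Angstrom (inclusive)
#' @param docking_contact_cutoff docked-pose contact cutoff, Angstrom
#'   (strict)
#' @param cluster_cutoff conformational clustering cutoff, nm
#' @param bound_frames frames of the synthetic bound trajectory
#' @param docking extra overrides passed to [docking_config()]
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("pepmpc_"),
                            peptide_sequence = "HWDDD",
                            n_runs = 8, run_length = 0.1,
                            n_record = 50,
                            contact_cutoff = 3.0,
                            docking_contact_cutoff = 3.5,
                            cluster_cutoff = 0.1,
                            bound_frames = 400,
                            docking = list()) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline
#'
#' Stages: (i) build the coarse peptide (extended + horseshoe
#' conformers) and the Au-MPC model with counterion accounting;
#' (ii) flexible BD docking and GROMOS pose clustering into a docking
#' table; (iii) synthetic bound-complex trajectory seeded from the top
#' pose's contact patch (documented stand-in for atomistic refinement);
#' (iv) association, MSD, contact and conformational-clustering
#' analyses; (v) a machine-readable report bundle. Deterministic under
#' `config$seed`.
#'
#' @param config a `pipeline_config`
#' @return (invisibly) the summary list; files are written under
#'   `config$out_dir` (`docking_table.csv`, `association.csv`,
#'   `contacts.csv`, `summary.json`, `log.txt`, `bound_traj.gro`)
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat(sprintf("pepmpc pipeline, seed %d\n", config$seed), file = log_path)

  stage <- "build"
  result <- tryCatch({
    pep <- build_peptide(config$peptide_sequence,
                         c("extended", "horseshoe"))
    clus <- build_nanocluster()
    q_pep <- pep$net_charge
    q_clus <- nanocluster_charge(clus)
    ions <- counterion_count(q_pep + q_clus)
    logf("stage build: peptide %s (q=%+d), cluster q=%+g, ions Na=%d Cl=%d",
         pep$sequence, q_pep, q_clus, ions["n_Na"], ions["n_Cl"])

    stage <- "dock"
    dock_args <- list(n_runs = config$n_runs,
                      run_length = config$run_length,
                      n_record = config$n_record, rng_seed = config$seed,
                      start_separation = 40, record_every = 5,
                      escape_radius = 150)
    dock_args[names(config$docking)] <- config$docking
    dcfg <- do.call(docking_config, dock_args)
    dock <- run_docking(pep, clus, dcfg)
    logf("stage dock: %d poses recorded over %d steps",
         length(dock$poses), dock$n_steps)
    table <- if (length(dock$poses))
      cluster_poses(dock$poses, pep) else NULL
    if (!is.null(table))
      utils::write.csv(table,
                       file.path(config$out_dir, "docking_table.csv"),
                       row.names = FALSE)

    stage <- "synthesize"
    patch <- integer(0)
    if (length(dock$poses)) {
      top <- dock$poses[[1]]
      pepc <- pose_coords(top, pep)
      r <- .cdist(bead_coords(pepc),
                  bead_coords(clus$beads)[clus$terminal_idx, , drop = FALSE])
      patch <- which(apply(r, 2, min) < ang_to_nm(8))
    }
    if (!length(patch)) patch <- c(1L, 2L, 3L)
    spec <- generator_spec("bound_complex", dt = 10,
                           n_frames = config$bound_frames,
                           seed = config$seed,
                           patch_ligand_ids = patch)
    synth <- gen_bound_complex(spec, pep, clus)
    write_trajectory(synth$trajectory,
                     file.path(config$out_dir, "bound_traj.gro"), "gro")
    logf("stage synthesize: bound complex, patch = {%s}",
         paste(patch, collapse = ","))

    stage <- "analyze"
    prof <- association_profile(synth$trajectory)
    utils::write.csv(
      data.frame(time = prof$times, d_com = prof$d_com,
                 theta = prof$theta, phi = prof$phi),
      file.path(config$out_dir, "association.csv"), row.names = FALSE)
    pos <- com_series(synth$trajectory, "peptide")
    mres <- msd(pos, synth$trajectory$times)
    ct <- ligand_contacts(synth$trajectory, cutoff = config$contact_cutoff)
    utils::write.csv(
      data.frame(ligand_id = ct$ligand_ids, P = unname(ct$P)),
      file.path(config$out_dir, "contacts.csv"), row.names = FALSE)
    high_P <- ct$ligand_ids[ct$P > 0.5]
    cl <- gromos_cluster(synth$trajectory,
                         cutoff = config$cluster_cutoff,
                         molecule = "peptide",
                         stride = max(1, config$bound_frames %/% 200))
    logf("stage analyze: alpha=%.3f, D=%.3e, %d contact ligands, %d clusters",
         mres$alpha, mres$D_fit, length(high_P), length(cl$sizes))

    summary <- list(
      seed = config$seed,
      sequence = pep$sequence,
      peptide_charge = q_pep,
      cluster_charge = q_clus,
      counterions = as.list(ions),
      docking = list(n_poses = length(dock$poses),
                     visit_fractions = as.list(dock$visit_fractions),
                     best_U_repr = if (length(dock$energies))
                       min(dock$energies) else NA),
      bound = list(patch = as.list(sort(patch)),
                   recovered_patch = as.list(sort(high_P)),
                   alpha = mres$alpha, D_fit = mres$D_fit,
                   mean_d_com = mean(prof$d_com)),
      clustering = list(sizes = as.list(cl$sizes))
    )
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    logf("done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
    summary
  }, error = function(e) {
    logf("FAILED at stage %s: %s", stage, conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

#' Command-line entry point
#'
#' Subcommands: `run --config FILE [--out DIR] [--seed N]`,
#' `synth --kind KIND --out FILE [--truth FILE] [--seed N] ...`,
#' `dock --peptide SEQ --out FILE [--n-runs N] [--seed N]`,
#' `analyze --traj FILE --format gro --n-peptide N --out DIR`,
#' `contacts --traj FILE --n-peptide N [--cutoff A] --out FILE`,
#' `cluster --traj FILE [--cutoff NM] --out FILE`,
#' `gr --traj FILE --sel-a mol:name --sel-b mol:residue:i --out FILE`.
#'
#' @param args character vector (defaults to the process arguments)
#' @return exit status, invisibly: 0 ok, 1 validation error, 2 runtime
#' @export
pepmpc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (!length(i)) return(default)
    if (i[1] == length(args)) stop("missing value for ", flag)
    args[i[1] + 1]
  }
  status <- tryCatch({
    if (!length(args)) stop("usage: pepmpc <run|synth|dock|analyze|contacts|cluster> ...")
    cmd <- args[1]; args <- args[-1]
    seed <- as.integer(opt("--seed", "1"))
    switch(cmd,
      run = {
        cfg_file <- opt("--config")
        overrides <- if (!is.null(cfg_file)) parse_config(cfg_file) else list()
        out <- opt("--out", overrides$out_dir %||% "pepmpc_out")
        known <- names(formals(pipeline_config))
        overrides <- overrides[intersect(names(overrides), known)]
        cfg <- do.call(pipeline_config,
                       c(list(seed = seed, out_dir = out), overrides))
        run_pipeline(cfg)
      },
      synth = {
        kind <- opt("--kind") %||% stop("synth needs --kind")
        out <- opt("--out") %||% stop("synth needs --out")
        n <- as.integer(opt("--n-frames", "500"))
        dt <- as.numeric(opt("--dt", "10"))
        res <- switch(kind,
          free_diffusion = gen_free_diffusion(generator_spec(
            kind, dt = dt, n_frames = n, seed = seed,
            D_trans = as.numeric(opt("--D-trans", "0.27e-5")))),
          staged_association = gen_staged_association(generator_spec(
            kind, dt = dt, n_frames = n, seed = seed,
            stage_distances = c(25, 17, 16),
            stage_frames = rep(ceiling(n / 3), 3))),
          conformer_chain = gen_conformer_chain(generator_spec(
            kind, dt = dt, n_frames = n, seed = seed,
            switch_rate = as.numeric(opt("--switch-rate", "1"))),
            opt("--sequence", "HWDDD")),
          stop("unsupported synth kind: ", kind))
        write_trajectory(res$trajectory, out, "gro")
        truth_file <- opt("--truth")
        if (!is.null(truth_file))
          jsonlite::write_json(res$truth[setdiff(names(res$truth), "spec")],
                               truth_file, auto_unbox = TRUE, digits = NA)
        invisible(NULL)
      },
      dock = {
        seq_ <- opt("--peptide") %||% stop("dock needs --peptide")
        out <- opt("--out") %||% stop("dock needs --out")
        pep <- build_peptide(seq_, c("extended", "horseshoe"))
        clus <- build_nanocluster()
        dcfg <- docking_config(n_runs = as.integer(opt("--n-runs", "5")),
                               run_length = as.numeric(opt("--run-length", "0.02")),
                               n_record = 50, rng_seed = seed)
        dock <- run_docking(pep, clus, dcfg)
        tab <- cluster_poses(dock$poses, pep)
        utils::write.csv(tab, out, row.names = FALSE)
        invisible(NULL)
      },
      analyze = {
        traj <- .cli_read_traj(opt, stop_if_missing = TRUE)
        out <- opt("--out", "metrics")
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        prof <- association_profile(traj)
        utils::write.csv(
          data.frame(time = prof$times, d_com = prof$d_com,
                     theta = prof$theta, phi = prof$phi),
          file.path(out, "association.csv"), row.names = FALSE)
        mres <- msd(com_series(traj, "peptide"), traj$times)
        jsonlite::write_json(
          list(D_fit = mres$D_fit, alpha = mres$alpha),
          file.path(out, "msd.json"), auto_unbox = TRUE, digits = NA)
        invisible(NULL)
      },
      contacts = {
        traj <- .cli_read_traj(opt, stop_if_missing = TRUE)
        out <- opt("--out") %||% stop("contacts needs --out")
        ct <- ligand_contacts(traj,
                              cutoff = as.numeric(opt("--cutoff", "3.0")))
        utils::write.csv(data.frame(ligand_id = ct$ligand_ids,
                                    P = unname(ct$P)),
                         out, row.names = FALSE)
        invisible(NULL)
      },
      gr = {
        traj <- .cli_read_traj(opt, stop_if_missing = TRUE)
        out <- opt("--out") %||% stop("gr needs --out")
        selA <- .cli_selector(traj, opt("--sel-a") %||%
                                stop("gr needs --sel-a"))
        selB <- .cli_selector(traj, opt("--sel-b") %||%
                                stop("gr needs --sel-b"))
        g <- pair_correlation(traj, selA, selB,
                              r_max = as.numeric(opt("--r-max", "10")),
                              shell_width = as.numeric(opt("--shell-width",
                                                           "0.5")))
        utils::write.csv(data.frame(r = g$r_centers, g = g$g), out,
                         row.names = FALSE)
        invisible(NULL)
      },
      cluster = {
        traj <- .cli_read_traj(opt, stop_if_missing = TRUE)
        out <- opt("--out") %||% stop("cluster needs --out")
        cl <- gromos_cluster(traj, cutoff = as.numeric(opt("--cutoff", "0.1")),
                             molecule = names(traj$molecules)[1])
        utils::write.csv(data.frame(cluster = seq_along(cl$sizes),
                                    size = cl$sizes,
                                    representative = cl$representatives),
                         out, row.names = FALSE)
        invisible(NULL)
      },
      stop("unknown subcommand: ", cmd))
    0L
  }, error = function(e) {
    message("pepmpc error: ", conditionMessage(e))
    if (grepl("usage:|needs|not found|unknown", conditionMessage(e))) 1L else 2L
  })
  invisible(status)
}

# "molecule:name" or "molecule:residue:<index>" selector mini-language
.cli_selector <- function(traj, spec) {
  parts <- strsplit(spec, ":")[[1]]
  if (length(parts) == 3 && parts[2] == "residue")
    return(select_beads(traj, molecule = parts[1],
                        residue_index = as.integer(parts[3])))
  if (length(parts) == 2)
    return(select_beads(traj, molecule = parts[1], name = parts[2]))
  stop("bad selector: ", spec)
}

.cli_read_traj <- function(opt, stop_if_missing = FALSE) {
  path <- opt("--traj")
  if (is.null(path)) {
    if (stop_if_missing) stop("missing --traj FILE")
    return(NULL)
  }
  fmt <- opt("--format", "gro")
  traj <- read_trajectory(path, fmt, dt = as.numeric(opt("--dt", "10")))
  n_pep <- opt("--n-peptide")
  if (!is.null(n_pep)) {
    n_pep <- as.integer(n_pep)
    nb <- dim(traj$coords)[2]
    traj$molecules <- list(peptide = seq_len(n_pep),
                           cluster = (n_pep + 1):nb)
  }
  traj
}

`%||%` <- function(a, b) if (is.null(a)) b else a
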