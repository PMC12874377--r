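#' Pipeline configuration
#'
#' Collects every knob of the three-stage screening workflow with the
#' protocol defaults: keep the `M = 100` lowest static-energy
#' structures, prescreen with harmonic lattice dynamics on a 0-400 K
#' grid, advance the `top_k = 5` most stable at 300 K, then refine with
#' PSCP free energies against the rank-1 reference.
#'
#' @param set a `toy_polymorph_set`, or `NULL` when `structures`/`ff`
#'   are given directly.
#' @param structures named list of [crystal_structure()] (used when
#'   `set` is `NULL`).
#' @param ff a [force_field()].
#' @param liquid optional liquid-box [crystal_structure()] for melting
#'   analysis.
#' @param M prescreen size (lowest static energies kept), default 100.
#' @param T_select prescreen ranking temperature (K), default 300.
#' @param top_k structures advancing to PSCP, default 5.
#' @param T_grid lattice-dynamics temperature grid (K).
#' @param n_sc supercell factor for lattice dynamics (`NULL` = auto).
#' @param pscp list of PSCP controls: `enabled`, `T_ref`, `T_grid`
#'   (temperature grid for the reduced free-energy chains), `schedule`
#'   (overrides for [build_schedule()]), `n_sweeps`, `thin`, `melt`.
#' @param seed base RNG seed.
#' @param out_dir optional output/cache directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(set = NULL, structures = NULL, ff = NULL,
                            liquid = NULL, M = 100, T_select = 300,
                            top_k = 5, T_grid = seq(0, 400, 20),
                            n_sc = NULL,
                            pscp = list(), seed = 1, out_dir = NULL) {
  if (!is.null(set)) {
    structures <- set$structures
    ff <- set$ff
    liquid <- set$liquid
  }
  if (is.null(structures) || is.null(ff)) {
    stop("need either a toy_polymorph_set or structures + ff")
  }
  if (M < top_k || top_k < 1) stop("need M >= top_k >= 1")
  if (any(diff(T_grid) <= 0)) stop("T_grid must be strictly increasing")
  pscp <- utils::modifyList(
    list(enabled = TRUE, T_ref = 350,
         T_grid = seq(T_select - 100, T_select + 100, 25),
         schedule = list(n_lambda = 12, n_extra = 4, n_wfl = 8,
                         n_vol = 8),
         n_sweeps = 600, thin = 4, melt = FALSE, K_weak = 0.55,
         K_liquid = 0.4),
    pscp)
  if (!(pscp$T_ref %in% pscp$T_grid)) {
    pscp$T_grid <- sort(unique(c(pscp$T_grid, pscp$T_ref)))
  }
  structure(list(structures = structures, ff = ff, liquid = liquid,
                 M = M, T_select = T_select, top_k = top_k,
                 T_grid = T_grid, n_sc = n_sc, pscp = pscp,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(cfg, stage) {
  x <- cfg
  x$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(list(x, stage), tmp, version = 2)
  unname(tools::md5sum(tmp))
}

cache_get <- function(cfg, stage) {
  if (is.null(cfg$out_dir)) return(NULL)
  f <- file.path(cfg$out_dir, "cache",
                 paste0(stage, "-", config_hash(cfg, stage), ".rds"))
  if (file.exists(f)) readRDS(f) else NULL
}

cache_put <- function(cfg, stage, value) {
  if (is.null(cfg$out_dir)) return(invisible(NULL))
  d <- file.path(cfg$out_dir, "cache")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  saveRDS(value, file.path(d, paste0(stage, "-",
                                     config_hash(cfg, stage), ".rds")),
          version = 2)
  invisible(NULL)
}

## build the sampling system for a structure: anchored toys morph their
## springs toward K2 along the path; plain crystals get Gaussian
## restraints at their lattice sites instead
pscp_system <- function(s, ff, K2 = NULL, epsilon = 20.92,
                        sigma = 0.5) {
  anchored <- !is.null(s$anchors)
  rest <- if (!anchored) {
    restraint_spec(epsilon, sigma, atom_table(s)$xyz)
  } else NULL
  sys <- toy_system(s, ff,
                    anchor_K = if (anchored) s$anchors$K else NULL,
                    anchor_u0 = if (anchored) s$anchors$u0 else 0,
                    restraint = rest)
  if (!is.null(K2) && anchored) {
    sys$anchor_K2 <- matrix(K2, nrow(sys$anchors$K), 3)
  }
  sys
}

#' Run the three-stage screening pipeline
#'
#' Stage 1 ranks every input by static lattice energy and keeps the
#' lowest `M`. Stage 2 computes harmonic lattice-dynamics Helmholtz
#' curves, eliminates dynamically unstable structures with the failure
#' reason, ranks the survivors at `T_select` and advances the top
#' `top_k`. Stage 3 runs PSCP solid-solid free energies of every
#' advanced candidate against the rank-1 reference, extrapolates
#' `dG(T)` over the PSCP temperature grid, and locates transition
#' temperatures; optionally it also runs a melting leg against the
#' liquid box. Per-structure failures are recorded and the pipeline
#' continues with the survivors. With an `out_dir`, completed stages
#' are cached by config hash and reused on re-runs.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose print stage progress.
#' @return An object of class `pipeline_report`: `stage1` (data.frame),
#'   `stage2` (a [screen_and_rank()] report), `stage3` (per-candidate
#'   list with `result`, `curve`, `transition`), `melt` (optional),
#'   `eliminated`, `provenance`.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (verbose) message(...)
  prov <- list(seed = cfg$seed, hash = config_hash(cfg, "all"),
               time = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))

  ## ---- Stage 1: static lattice-energy ranking -----------------------
  s1 <- cache_get(cfg, "stage1")
  if (is.null(s1)) {
    say("stage 1: static lattice energies")
    u <- vapply(cfg$structures, function(s)
      tryCatch(static_energy(s, cfg$ff), error = function(e) NA_real_),
      0)
    s1 <- data.frame(id = names(cfg$structures), U_static = u,
                     rank = rank(u, ties.method = "first"),
                     kept = rank(u, ties.method = "first") <= cfg$M &
                       !is.na(u))
    cache_put(cfg, "stage1", s1)
  }
  keep_ids <- s1$id[s1$kept]
  elim <- data.frame(id = s1$id[!s1$kept],
                     stage = rep("stage1", sum(!s1$kept)),
                     reason = ifelse(is.na(s1$U_static[!s1$kept]),
                                     "energy evaluation failed",
                                     "above prescreen size M"))

  ## ---- Stage 2: HA-LD prescreen -------------------------------------
  s2 <- cache_get(cfg, "stage2")
  if (is.null(s2)) {
    say("stage 2: lattice-dynamics prescreening")
    curves <- helmholtz_curves(cfg$structures[keep_ids], cfg$ff,
                               T_grid = cfg$T_grid, n_sc = cfg$n_sc)
    s2 <- screen_and_rank(curves, T_select = cfg$T_select,
                          top_k = cfg$top_k)
    cache_put(cfg, "stage2", s2)
  }
  if (nrow(s2$eliminated)) {
    elim <- rbind(elim, data.frame(id = s2$eliminated$id,
                                   stage = "stage2",
                                   reason = s2$eliminated$reason))
  }
  adv <- s2$ranking$id[s2$ranking$advance]

  ## ---- Stage 3: PSCP refinement -------------------------------------
  s3 <- NULL; melt <- NULL
  if (cfg$pscp$enabled && length(adv) >= 1) {
    s3 <- cache_get(cfg, "stage3")
    if (is.null(s3)) {
      say("stage 3: PSCP free energies")
      s3 <- tryCatch(
        pscp_solid_solid_analysis(cfg, adv),
        error = function(e) {
          list(error = conditionMessage(e))
        })
      cache_put(cfg, "stage3", s3)
    }
    if (cfg$pscp$melt && !is.null(cfg$liquid)) {
      melt <- cache_get(cfg, "melt")
      if (is.null(melt)) {
        say("stage 3b: melting analysis")
        melt <- tryCatch(pscp_melt_analysis(cfg, adv[1]),
                         error = function(e)
                           list(error = conditionMessage(e)))
        cache_put(cfg, "melt", melt)
      }
    }
  }
  rep <- structure(list(stage1 = s1, stage2 = s2, stage3 = s3,
                        melt = melt, eliminated = elim,
                        provenance = prov, config = cfg),
                   class = "pipeline_report")
  if (!is.null(cfg$out_dir)) report_writers(rep, cfg$out_dir)
  rep
}

## PSCP solid-solid legs of the pipeline: every advanced candidate
## against the rank-1 reference
pscp_solid_solid_analysis <- function(cfg, adv) {
  p <- cfg$pscp
  ref_id <- adv[1]
  sched_l <- build_schedule("S->DWF", p$schedule)
  kBT <- .const$kB
  ## per-structure S->DWF stage + volume stage + temperature chain
  leg <- function(id, seed_off) {
    s <- cfg$structures[[id]]
    sys <- pscp_system(s, cfg$ff, K2 = p$K_weak)
    st_dwf <- pscp_stage(sys, sched_l, p$T_ref,
                         n_sweeps = p$n_sweeps, thin = p$thin,
                         seed = cfg$seed + seed_off)
    ## volume stage: DWF (weak springs, solid volume) -> common WF
    dwf_struct <- s
    dwf_struct$anchors <- NULL
    sys_dwf <- toy_system(dwf_struct, cfg$ff, anchor_K = p$K_weak)
    V_solid <- cell_volume(s$cell)
    V_wf <- if (!is.null(cfg$liquid)) {
      cell_volume(cfg$liquid$cell) / cfg$liquid$Z * s$Z
    } else 1.3 * V_solid
    sched_v <- build_schedule("DWF->WF",
                              utils::modifyList(p$schedule,
                                                list(V_solid = V_solid,
                                                     V_liquid = V_wf)))
    st_vol <- pscp_stage(sys_dwf, sched_v, p$T_ref,
                         n_sweeps = p$n_sweeps, thin = p$thin,
                         seed = cfg$seed + seed_off + 1000)
    ## temperature chain for the reduced free energies
    trajs <- lapply(seq_along(p$T_grid), function(i)
      run_nvt(sys, sim_state(p$T_grid[i], ensemble = "NVT"),
              n_sweeps = p$n_sweeps, thin = p$thin,
              seed = cfg$seed + seed_off + 2000 + i,
              store_configs = TRUE))
    list(id = id, s_dwf = st_dwf, dwf_wf = st_vol, trajs = trajs,
         sys = sys)
  }
  legs <- list()
  for (i in seq_along(adv)) {
    legs[[adv[i]]] <- leg(adv[i], 10000 * i)
  }
  out <- list(reference = ref_id, candidates = list())
  for (id in setdiff(adv, ref_id)) {
    res <- pscp_combine(list(s1_dwf = legs[[ref_id]]$s_dwf,
                             dwf1_wf = legs[[ref_id]]$dwf_wf,
                             sj_dwf = legs[[id]]$s_dwf,
                             dwfj_wf = legs[[id]]$dwf_wf),
                        kind = "solid_solid", T_ref = p$T_ref)
    dG_ref <- pv_correct(res$dA, 1, 0)   # isochoric toys: dV ~ 0
    dft <- temperature_mbar(legs[[ref_id]]$trajs,
                            rep(list(legs[[ref_id]]$sys),
                                length(p$T_grid)),
                            legs[[id]]$trajs,
                            rep(list(legs[[id]]$sys),
                                length(p$T_grid)),
                            p$T_grid)
    curve <- gibbs_vs_temperature(dG_ref, dft, p$T_ref,
                                  dG_ref_se = res$se)
    tr <- find_transition(curve)
    out$candidates[[id]] <- list(result = res, df_table = dft,
                                 curve = curve, transition = tr)
  }
  out$legs_meta <- lapply(legs, function(l)
    list(id = l$id, dA_s_dwf = l$s_dwf$dA, se_s_dwf = l$s_dwf$se,
         dA_dwf_wf = l$dwf_wf$dA, se_dwf_wf = l$dwf_wf$se))
  out
}

## melting leg: reference candidate vs the liquid box
pscp_melt_analysis <- function(cfg, id) {
  p <- cfg$pscp
  s <- cfg$structures[[id]]
  liq <- cfg$liquid
  sys_s <- pscp_system(s, cfg$ff, K2 = p$K_weak)
  st_dwf <- pscp_stage(sys_s, build_schedule("S->DWF", p$schedule),
                       p$T_ref, n_sweeps = p$n_sweeps, thin = p$thin,
                       seed = cfg$seed + 31)
  dwf_struct <- s; dwf_struct$anchors <- NULL
  sys_dwf <- toy_system(dwf_struct, cfg$ff, anchor_K = p$K_weak)
  V_solid <- cell_volume(s$cell)
  V_liq <- cell_volume(liq$cell) / liq$Z * s$Z
  st_vol <- pscp_stage(sys_dwf,
                       build_schedule("DWF->WF",
                                      utils::modifyList(
                                        p$schedule,
                                        list(V_solid = V_solid,
                                             V_liquid = V_liq))),
                       p$T_ref, n_sweeps = p$n_sweeps, thin = p$thin,
                       seed = cfg$seed + 32)
  sys_l <- pscp_system(liq, cfg$ff, K2 = p$K_weak)
  st_wfl <- pscp_stage(sys_l, build_schedule("WF->L", p$schedule),
                       p$T_ref, n_sweeps = p$n_sweeps, thin = p$thin,
                       seed = cfg$seed + 33, control = list())
  res <- pscp_combine(list(s_dwf = st_dwf, dwf_wf = st_vol,
                           wf_l = st_wfl),
                      kind = "melt", T_ref = p$T_ref)
  trajs_s <- lapply(seq_along(p$T_grid), function(i)
    run_nvt(sys_s, sim_state(p$T_grid[i], ensemble = "NVT"),
            n_sweeps = p$n_sweeps, thin = p$thin,
            seed = cfg$seed + 40 + i, store_configs = TRUE))
  trajs_l <- lapply(seq_along(p$T_grid), function(i)
    run_nvt(sys_l, sim_state(p$T_grid[i], ensemble = "NVT"),
            n_sweeps = p$n_sweeps, thin = p$thin,
            seed = cfg$seed + 80 + i, store_configs = TRUE))
  dft <- temperature_mbar(trajs_s, rep(list(sys_s), length(p$T_grid)),
                          trajs_l, rep(list(sys_l), length(p$T_grid)),
                          p$T_grid)
  curve <- gibbs_vs_temperature(pv_correct(res$dA, 1, 0), dft, p$T_ref,
                                dG_ref_se = res$se)
  deltas <- phase_deltas(trajs_s, trajs_l, p$T_grid)
  tr <- find_transition(curve, deltas)
  list(id = id, result = res, curve = curve, transition = tr,
       deltas = deltas)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n-- stage 1 (static lattice energy):\n")
  print(x$stage1, row.names = FALSE)
  cat("-- stage 2 (HA-LD screening):\n")
  print(x$stage2)
  if (!is.null(x$stage3) && is.null(x$stage3$error)) {
    cat("-- stage 3 (PSCP vs ", x$stage3$reference, "):\n", sep = "")
    for (id in names(x$stage3$candidates)) {
      cnd <- x$stage3$candidates[[id]]
      cat(sprintf("  %s: dA(T_ref) = %.4f +/- %.4f kJ/mol; ", id,
                  cnd$result$dA, cnd$result$se))
      if (cnd$transition$found) {
        cat(sprintf("T* = %.1f +/- %.1f K\n", cnd$transition$T_star,
                    cnd$transition$dT_star))
      } else cat("no transition on grid\n")
    }
  }
  invisible(x)
}

#' Format a value with its uncertainty in parentheses
#'
#' Rounds the uncertainty to one significant digit and the value to the
#' matching decimal place: `(322, 9) -> "322(9)"`,
#' `(2.74, 0.08) -> "2.74(8)"`.
#'
#' @param value,sigma numeric scalars; `sigma >= 0`.
#' @return character.
#' @export
format_uncertainty <- function(value, sigma) {
  if (is.na(sigma) || sigma <= 0) return(format(value))
  d <- -floor(log10(sigma))
  s1 <- round(sigma, d)
  if (s1 >= 10^(-d + 1)) { d <- d - 1; s1 <- round(sigma, d) }
  v1 <- round(value, d)
  if (d <= 0) {
    sprintf("%.0f(%.0f)", v1, s1)
  } else {
    sprintf("%.*f(%.0f)", d, v1, s1 * 10^d)
  }
}

#' Write pipeline result tables
#'
#' Emits the report as plain-text artifacts under `dir`: a lattice
#' parameter/density/relative-energy table (`table_structures.tsv`), a
#' transition-property table with parenthesised uncertainties
#' (`table_transitions.tsv`), a decomposition table when available
#' (`table_decomposition.tsv`), and a JSON summary
#' (`summary.json`) that reloads into equal result objects via
#' [jsonlite::read_json()].
#'
#' @param rep a `pipeline_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
report_writers <- function(rep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- rep$config
  ## structures table
  rows <- lapply(names(cfg$structures), function(id) {
    s <- cfg$structures[[id]]
    mass <- sum(s$molecules[[1]]$mass)
    r2 <- rep$stage2$ranking
    data.frame(id = id, a = s$cell$a, b = s$cell$b, c = s$cell$c,
               alpha = s$cell$alpha, beta = s$cell$beta,
               gamma = s$cell$gamma,
               density = compute_density(s, mass),
               U_static = rep$stage1$U_static[rep$stage1$id == id],
               dA_LD_0K = if (id %in% r2$id && 0 %in% rep$stage2$T_grid)
                 rep$stage2$dA_curves[match(0, rep$stage2$T_grid),
                                      match(id, colnames(rep$stage2$dA_curves))]
               else NA_real_,
               stable = !(id %in% rep$stage2$eliminated$id))
  })
  utils::write.table(do.call(rbind, rows),
                     file.path(dir, "table_structures.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ## transitions table
  trows <- list()
  if (!is.null(rep$stage3) && is.null(rep$stage3$error)) {
    for (id in names(rep$stage3$candidates)) {
      tr <- rep$stage3$candidates[[id]]$transition
      trows[[length(trows) + 1]] <- data.frame(
        pair = paste0(rep$stage3$reference, "->", id),
        kind = "solid-solid",
        T_star = if (tr$found) format_uncertainty(tr$T_star,
                                                  tr$dT_star) else "none",
        dH = "", dCp = "")
    }
  }
  if (!is.null(rep$melt) && is.null(rep$melt$error)) {
    tr <- rep$melt$transition
    trows[[length(trows) + 1]] <- data.frame(
      pair = paste0(rep$melt$id, "->liquid"), kind = "melting",
      T_star = if (tr$found) format_uncertainty(tr$T_star, tr$dT_star)
      else "none",
      dH = if (tr$found && !is.null(tr$dH))
        format_uncertainty(tr$dH, tr$dH_se) else "",
      dCp = if (tr$found && !is.null(tr$dCp))
        format_uncertainty(tr$dCp, tr$dCp_se) else "")
  }
  ttab <- if (length(trows)) do.call(rbind, trows) else
    data.frame(pair = character(), kind = character(),
               T_star = character(), dH = character(),
               dCp = character())
  utils::write.table(ttab, file.path(dir, "table_transitions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ## JSON summary
  summ <- list(
    provenance = rep$provenance,
    stage1 = rep$stage1,
    stage2 = list(ranking = rep$stage2$ranking,
                  eliminated = rep$stage2$eliminated,
                  T_select = rep$stage2$T_select),
    eliminated = rep$eliminated,
    stage3 = if (!is.null(rep$stage3) && is.null(rep$stage3$error)) {
      list(reference = rep$stage3$reference,
           candidates = lapply(rep$stage3$candidates, function(cnd) {
             list(dA = cnd$result$dA, se = cnd$result$se,
                  T_ref = cnd$result$T_ref,
                  curve = cnd$curve,
                  transition = if (cnd$transition$found)
                    list(T_star = cnd$transition$T_star,
                         dT_star = cnd$transition$dT_star)
                  else list(T_star = NULL))
           }))
    } else NULL)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(dir)
}
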