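#' @export
print.fitness_landscape <- function(x, ...) {
  n_epi <- sum(x$fij != 0)
  cat(sprintf("fitness_landscape: L = %d, f0 = %g\n", x$L, x$f0))
  cat(sprintf("  fi:  sd = %.4g (sigma_fi = %s)\n", stats::sd(x$fi),
              if (is.null(x$meta$sigma_fi)) "?" else x$meta$sigma_fi))
  cat(sprintf("  fij: %d non-zero pairs (sigma_fij = %s)\n", n_epi,
              if (is.null(x$meta$sigma_fij)) "?" else x$meta$sigma_fij))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: N = %d, L = %d, T = %d, r = %g, mu = %g, %d replicate(s), seed = %d\n",
    x$N, x$L, x$T, x$r, x$mu, x$n_replicates, x$seed))
  cat(sprintf("  init = %s, sample_fraction = %g, c = %g\n",
              x$init_mode, x$sample_fraction, x$c))
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  gens <- generations(x)
  cat(sprintf("trajectory: replicate %d, %d recorded generations (%d..%d)\n",
              x$replicate_id, length(gens), min(gens), max(gens)))
  invisible(x)
}

#' @export
print.inferred_landscape <- function(x, ...) {
  cat(sprintf("inferred_landscape: method = %s%s, L = %d\n", x$method,
              if (!is.null(x$variant)) paste0(" (", x$variant, ")") else "",
              x$L))
  cat(sprintf("  fi*:  range [%.4g, %.4g]\n", min(x$fi_star), max(x$fi_star)))
  if (!is.null(x$fij_star))
    cat(sprintf("  fij*: sd = %.4g\n", stats::sd(x$fij_star[upper.tri(x$fij_star)])))
  else cat("  fij*: not inferred (additive-only)\n")
  invisible(x)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %d genotypes ranked, elite size %d\n",
              x$universe_size, x$elite_size))
  for (nm in names(x$estimates)) {
    e <- x$estimates[[nm]]
    cat(sprintf("  %-14s spearman_all = %.3f, spearman_top5 = %.3f\n",
                nm, e$spearman_all, e$spearman_top5))
  }
  cat(sprintf("  KS initial vs final (total/additive/epistatic): %.3f / %.3f / %.3f\n",
              x$ks_initial_vs_final[["total"]],
              x$ks_initial_vs_final[["additive"]],
              x$ks_initial_vs_final[["epistatic"]]))
  invisible(x)
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario '%s' (seed %d): N = %d, L = %d, T = %d, r = %g, mu = %g\n",
              x$name, x$seed, x$N, x$L, x$T, x$r, x$mu))
  cat(sprintf("  sigma_fi = %g, sigma_fij = %g, replicates at {%s}, tQLE variant = %s\n",
              x$sigma_fi, x$sigma_fij,
              paste(x$replicate_counts, collapse = ", "), x$variant))
  invisible(x)
}
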