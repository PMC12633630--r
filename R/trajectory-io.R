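## Trajectory exchange formats.
##
## Dialect A ("table"): delimited text with columns
##   replicate, generation, genotype, count
## where genotype is a string over a declared alphabet ("01" or "+-").
##
## Dialect B ("fasta"): one record per unique genotype per generation with
## header rep<k>|t<gen>|n<count>, sequence over {A, T} mapping -1 -> A,
## +1 -> T.  A sidecar JSON file (<path>.meta.json) declares the mapping and
## the configuration so the round trip is self-describing.

geno_to_string <- function(S, alphabet = c("01", "+-")) {
  alphabet <- match.arg(alphabet)
  chars <- if (alphabet == "01") c("0", "1") else c("-", "+")
  apply(S, 1L, function(row) paste0(chars[(row + 1L) / 2L + 1L], collapse = ""))
}

string_to_geno <- function(strings, alphabet = c("01", "+-")) {
  alphabet <- match.arg(alphabet)
  plus <- if (alphabet == "01") "1" else "+"
  mat <- do.call(rbind, strsplit(strings, ""))
  matrix(ifelse(mat == plus, 1L, -1L), nrow(mat), ncol(mat))
}

#' Write trajectories as a delimited table
#'
#' @param trajs a `trajectory` or list of trajectories.
#' @param path output file path (tab-separated, with a `#` header line
#'   declaring the genotype alphabet).
#' @param alphabet `"01"` (0 = -1 allele, 1 = +1 allele) or `"+-"`.
#' @return `path`, invisibly.
#' @export
write_trajectory_table <- function(trajs, path, alphabet = c("01", "+-")) {
  alphabet <- match.arg(alphabet)
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr) {
    do.call(rbind, lapply(tr$records, function(rec)
      data.frame(replicate = tr$replicate_id, generation = rec$gen,
                 genotype = geno_to_string(rec$geno, alphabet),
                 count = rec$count)))
  })
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# fitbench trajectory table; genotype alphabet=", alphabet,
                    if (alphabet == "01") " (1 = +1 allele)" else ""), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read trajectories from a delimited table
#'
#' @param path file written by [write_trajectory_table()] (or any delimited
#'   file with the same columns; the alphabet is taken from the `#` header
#'   line, defaulting to `"01"`).
#' @param config optional [sim_config()] to attach to the trajectories.
#' @return list of `trajectory` objects, one per replicate id.
#' @export
read_trajectory_table <- function(path, config = NULL) {
  first <- readLines(path, n = 1L)
  alphabet <- if (grepl("alphabet=\\+-", first)) "+-" else "01"
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           colClasses = c("integer", "integer", "character",
                                          "integer"))
  split_tab <- split(tab, tab$replicate)
  lapply(split_tab, function(sub) {
    recs <- lapply(split(sub, sub$generation), function(g)
      list(gen = g$generation[1L],
           geno = string_to_geno(g$genotype, alphabet),
           count = g$count))
    recs <- recs[order(vapply(recs, `[[`, integer(1L), "gen"))]
    structure(list(replicate_id = sub$replicate[1L], config = config,
                   landscape_ref = NULL, records = unname(recs)),
              class = "trajectory")
  })
}

#' Write trajectories as FASTA
#'
#' One record per unique genotype per generation, header
#' `rep<k>|t<gen>|n<count>`, alphabet \{A, T\} with -1 -> A and +1 -> T.
#' The mapping and configuration are written to `<path>.meta.json`.
#'
#' @inheritParams write_trajectory_table
#' @return `path`, invisibly.
#' @export
write_trajectory_fasta <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  seqs <- list(); names_out <- character(0)
  for (tr in trajs) {
    for (rec in tr$records) {
      chars <- apply(rec$geno, 1L, function(row)
        paste0(c("A", "T")[(row + 1L) / 2L + 1L], collapse = ""))
      nm <- sprintf("rep%d|t%d|n%d", tr$replicate_id, rec$gen, rec$count)
      seqs <- c(seqs, as.list(chars))
      names_out <- c(names_out, nm)
    }
  }
  seqinr::write.fasta(lapply(seqs, function(s) strsplit(s, "")[[1L]]),
                      names = names_out, file.out = path, nbchar = 10000L)
  cfg <- trajs[[1L]]$config
  jsonlite::write_json(
    list(mapping = list(A = -1L, T = 1L),
         config = if (is.null(cfg)) NULL else unclass(cfg)),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read trajectories from FASTA written by [write_trajectory_fasta()]
#'
#' @param path FASTA file path.
#' @return list of `trajectory` objects.
#' @export
read_trajectory_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  headers <- names(fa)
  parts <- regmatches(headers,
                      regexec("^rep([0-9]+)\\|t([0-9]+)\\|n([0-9]+)$", headers))
  if (any(vapply(parts, length, integer(1L)) != 4L))
    stop_invalid("FASTA headers must have the form rep<k>|t<gen>|n<count>")
  info <- do.call(rbind, lapply(parts, function(p) as.integer(p[-1L])))
  seq_strings <- vapply(fa, function(s) as.character(s[[1L]]), character(1L))
  S <- do.call(rbind, strsplit(toupper(seq_strings), ""))
  S <- matrix(ifelse(S == "T", 1L, -1L), nrow(S), ncol(S))
  config <- NULL
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$config) && length(meta$config))
      config <- do.call(sim_config, meta$config[setdiff(names(meta$config), "")])
  }
  reps <- split(seq_len(nrow(info)), info[, 1L])
  lapply(reps, function(idx) {
    gens <- split(idx, info[idx, 2L])
    recs <- lapply(gens, function(ii)
      list(gen = info[ii[1L], 2L], geno = S[ii, , drop = FALSE],
           count = info[ii, 3L]))
    recs <- recs[order(vapply(recs, `[[`, integer(1L), "gen"))]
    structure(list(replicate_id = info[idx[1L], 1L], config = config,
                   landscape_ref = NULL, records = unname(recs)),
              class = "trajectory")
  })
}
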