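#' Configuration for the synthetic fixture generator
#'
#' Bundles the knobs of the synthetic data generator with defaults chosen
#' to emulate the statistical structure of a BLAST-based homology pipeline
#' at desk scale: chains of 80-250 residues; retained-hit counts around 30
#' for most chains with a minority of sparse-homology chains so both
#' homology branches are exercised; per-position Dirichlet-multinomial
#' alignment columns whose concentration spans strongly conserved to fully
#' variable sites; labels drawn from a logistic model at known
#' coefficients; label-consistent continuous accessibilities; half the
#' chains oligomeric with one-fifth of their residues interfacial.
#'
#' @param n_chains Number of query chains.
#' @param length_range Chain length range (inclusive).
#' @param hits_lambda Poisson mean of the subject-sequence count for
#'   well-homologized chains.
#' @param sparse_fraction Fraction of chains drawn with sparse homology
#'   (Poisson mean \code{sparse_lambda}), exercising the non-optimum
#'   branch.
#' @param sparse_lambda Poisson mean of hit counts for sparse chains.
#' @param log_conc_range Range of log10 Dirichlet concentration per
#'   alignment column; low values give conserved columns, high values
#'   variable ones.
#' @param gap_prob Per-position probability that a subject letter is a gap.
#' @param x_prob Per-position probability of an undefined (X) query
#'   residue.
#' @param true_model \code{logistic_fit} used as generative truth for the
#'   labels; default the published classic-model coefficients
#'   ([classic_model_1363()]).
#' @param rsa_threshold RSA threshold (percent) the generated labels and
#'   accessibilities are consistent with.
#' @param oligomer_fraction Fraction of chains marked oligomeric.
#' @param interfacial_fraction Fraction of oligomer residues made
#'   interfacial.
#' @param interfacial_delta_range Range of the single-chain minus complex
#'   accessibility increase (percentage points) at interfacial residues.
#' @param interfacial_label_noise Probability that an interfacial residue's
#'   label is flipped relative to what its descriptors predict, emulating
#'   the weaker descriptor-label coupling observed at interfaces.
#' @param bitscore_fraction,min_hits Filtering parameters the fixture is
#'   built to exercise.
#' @param seed Integer seed; fully determines the fixture.
#' @return A list of class \code{fixture_config}.
#' @export
fixture_config <- function(n_chains = 24L,
                           length_range = c(80L, 250L),
                           hits_lambda = 30,
                           sparse_fraction = 0.15,
                           sparse_lambda = 4,
                           log_conc_range = c(-1.5, 0.7),
                           gap_prob = 0.05,
                           x_prob = 0.005,
                           true_model = NULL,
                           rsa_threshold = 20,
                           oligomer_fraction = 0.5,
                           interfacial_fraction = 0.2,
                           interfacial_delta_range = c(5, 30),
                           interfacial_label_noise = 0.1,
                           bitscore_fraction = 0.4,
                           min_hits = 10L,
                           seed = 1L) {
  cfg <- list(n_chains = as.integer(n_chains),
              length_range = as.integer(length_range),
              hits_lambda = hits_lambda,
              sparse_fraction = sparse_fraction,
              sparse_lambda = sparse_lambda,
              log_conc_range = log_conc_range,
              gap_prob = gap_prob, x_prob = x_prob,
              true_model = true_model,
              rsa_threshold = rsa_threshold,
              oligomer_fraction = oligomer_fraction,
              interfacial_fraction = interfacial_fraction,
              interfacial_delta_range = interfacial_delta_range,
              interfacial_label_noise = interfacial_label_noise,
              bitscore_fraction = bitscore_fraction,
              min_hits = as.integer(min_hits),
              seed = as.integer(seed))
  fracs <- c(sparse_fraction, gap_prob, x_prob, oligomer_fraction,
             interfacial_fraction, interfacial_label_noise)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  class(cfg) <- "fixture_config"
  cfg
}

## Symmetric Dirichlet draw over the 20 amino-acid types.
rdirichlet20 <- function(conc) {
  g <- stats::rgamma(20L, shape = conc, rate = 1)
  if (all(g == 0)) g[sample.int(20L, 1L)] <- 1
  g / sum(g)
}

#' Simulate one query chain and its homolog hit set
#'
#' Draws a per-position column distribution over the 20 amino-acid types
#' from a symmetric Dirichlet whose concentration varies across positions
#' (mixing conserved and variable sites), samples the query and the aligned
#' subject letters from it, inserts gaps and rare undefined letters, and
#' assigns bit scores spread around the best hit so the relative bit-score
#' filter is exercised (some hits fall below a 40\% cut).
#'
#' @param chain_id Chain identifier.
#' @param length Chain length.
#' @param n_hits Number of subject sequences.
#' @param config A [fixture_config()] (only the column-model fields are
#'   used).
#' @return List with \code{query} (character vector, may contain X) and
#'   \code{hits} (data frame in [read_alignment_table()] layout).  Uses the
#'   current RNG state; seed under the caller's control.
#' @export
simulate_alignment <- function(chain_id, length, n_hits, config) {
  conc <- 10 ^ stats::runif(length, config$log_conc_range[1],
                            config$log_conc_range[2])
  colp <- vapply(conc, rdirichlet20, numeric(20L))  # 20 x length
  query <- AA_LETTERS[apply(colp, 2L, function(p) sample.int(20L, 1L,
                                                             prob = p))]
  xpos <- stats::runif(length) < config$x_prob
  query[xpos] <- "X"
  if (n_hits == 0L)
    return(list(query = query,
                hits = data.frame(qseqid = character(), sseqid = character(),
                                  bitscore = numeric(), qstart = integer(),
                                  qseq = character(), sseq = character(),
                                  stringsAsFactors = FALSE)))
  best <- stats::runif(1, 150, 400)
  bitscore <- round(c(best, best * stats::runif(n_hits - 1L, 0.25, 1)), 1)
  qseq_str <- paste(query, collapse = "")
  sseq <- character(n_hits)
  for (h in seq_len(n_hits)) {
    letters <- AA_LETTERS[apply(colp, 2L, function(p)
      sample.int(20L, 1L, prob = p))]
    gap <- stats::runif(length) < config$gap_prob
    letters[gap] <- "-"
    sseq[h] <- paste(letters, collapse = "")
  }
  list(query = query,
       hits = data.frame(qseqid = chain_id,
                         sseqid = sprintf("%s_hit%03d", chain_id,
                                          seq_len(n_hits)),
                         bitscore = bitscore, qstart = 1L,
                         qseq = qseq_str, sseq = sseq,
                         stringsAsFactors = FALSE))
}

#' Simulate buried/accessible labels from a known logistic model
#'
#' Draws each residue's label from a Bernoulli at the probability given by
#' the generative model, then draws a continuous relative accessibility
#' consistent with the label (uniform on \eqn{[0,}~threshold\eqn{)} for
#' buried, uniform on \eqn{[}threshold\eqn{, 100]} for accessible) so the
#' linear baseline can be tested against the same truth.  Records
#' incomplete for the generative model keep missing labels.
#'
#' @param records Residue data frame with descriptors filled.
#' @param true_model \code{logistic_fit} used as truth.
#' @param rsa_threshold Threshold (percent) for label-consistent RSA.
#' @return \code{records} with \code{label} and \code{rsa} columns.  Uses
#'   the current RNG state.
#' @export
simulate_labels <- function(records, true_model, rsa_threshold = 20) {
  p <- predict_proba(true_model, records)
  n <- nrow(records)
  y <- rep(NA_integer_, n)
  ok <- !is.na(p)
  y[ok] <- stats::rbinom(sum(ok), 1L, p[ok])
  rsa <- rep(NA_real_, n)
  acc <- ok & y == 1L
  bur <- ok & y == 0L
  rsa[acc] <- stats::runif(sum(acc), rsa_threshold, 100)
  rsa[bur] <- stats::runif(sum(bur), 0, rsa_threshold)
  records$label <- y
  records$rsa <- rsa
  records
}

#' Add oligomer context: complex accessibilities and interfacial residues
#'
#' Marks a fraction of chains oligomeric and, within them, a fraction of
#' residues interfacial.  Interfacial residues keep their label-consistent
#' accessibility as the complex-context value and get a single-chain value
#' raised by a positive delta (the partner chain buried them); with
#' probability \code{interfacial_label_noise} an interfacial residue's
#' label (and its complex accessibility) is flipped relative to what its
#' descriptors predict.  Non-interfacial oligomer residues have identical
#' accessibilities in both contexts.
#'
#' @param records Labeled residue data frame ([simulate_labels()] output).
#' @param config A [fixture_config()].
#' @return \code{records} with \code{oligomer}, \code{interfacial} and
#'   \code{rsa_complex} columns; for oligomer chains, \code{rsa} holds the
#'   single-chain value and \code{rsa_complex} the complex-context value
#'   the label follows.  Uses the current RNG state.
#' @export
simulate_oligomer_context <- function(records, config) {
  chains <- unique(records$chain_id)
  n_olig <- round(config$oligomer_fraction * length(chains))
  olig_chains <- if (n_olig > 0) sample(chains, n_olig) else character()
  records$oligomer <- records$chain_id %in% olig_chains
  records$rsa_complex <- ifelse(records$oligomer, records$rsa, NA_real_)
  records$interfacial <- ifelse(records$oligomer, FALSE, NA)
  cand <- which(records$oligomer & !is.na(records$label))
  n_intf <- round(config$interfacial_fraction * length(cand))
  if (n_intf > 0) {
    intf <- sample(cand, n_intf)
    records$interfacial[intf] <- TRUE
    thr <- config$rsa_threshold
    flip <- stats::runif(n_intf) < config$interfacial_label_noise
    if (any(flip)) {
      idx <- intf[flip]
      records$label[idx] <- 1L - records$label[idx]
      records$rsa_complex[idx] <- ifelse(
        records$label[idx] == 1L,
        stats::runif(length(idx), thr, 100),
        stats::runif(length(idx), 0, thr))
    }
    delta <- stats::runif(n_intf, config$interfacial_delta_range[1],
                          config$interfacial_delta_range[2])
    ## single-chain exposure is complex exposure plus the buried interface
    records$rsa[intf] <- pmin(records$rsa_complex[intf] + delta, 108)
  }
  records
}

#' Simulate a complete labeled residue set in memory
#'
#' Runs the whole generative pipeline at a fixed seed: chains and homolog
#' hits, bit-score filtering and descriptor computation through the regular
#' package code path, disorder propensities, model-drawn labels with
#' consistent accessibilities, and oligomer/interface structure.
#'
#' @param config A [fixture_config()].
#' @return List with \code{records} (the labeled descriptor table),
#'   \code{sequences}, \code{hits} (unfiltered) and \code{config}.
#' @export
simulate_records <- function(config = fixture_config()) {
  set.seed(config$seed)
  if (is.null(config$true_model)) config$true_model <- classic_model_1363()
  n <- config$n_chains
  ids <- sprintf("syn%03dA", seq_len(n))
  lens <- sample(config$length_range[1]:config$length_range[2], n,
                 replace = TRUE)
  sparse <- stats::runif(n) < config$sparse_fraction
  nhits <- ifelse(sparse,
                  stats::rpois(n, config$sparse_lambda),
                  stats::rpois(n, config$hits_lambda))
  sequences <- vector("list", n)
  names(sequences) <- ids
  hit_list <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulate_alignment(ids[i], lens[i], nhits[i], config)
    sequences[[i]] <- sim$query
    hit_list[[i]] <- sim$hits
  }
  hits <- do.call(rbind, hit_list)
  records <- suppressMessages(compute_descriptors(
    sequences, hits, bitscore_fraction = config$bitscore_fraction,
    min_hits = config$min_hits))
  lgdp <- data.frame(chain_id = records$chain_id,
                     position = records$position,
                     lgdp = round(stats::rbeta(nrow(records), 1.5, 6), 4))
  records <- suppressMessages(attach_lgdp(records, lgdp))
  records <- simulate_labels(records, config$true_model,
                             config$rsa_threshold)
  records <- simulate_oligomer_context(records, config)
  list(records = records, sequences = sequences, hits = hits,
       config = config)
}

## Format one synthetic chain as NACCESS-style .rsa text.
format_rsa_lines <- function(chain_id, aa, rsa) {
  keep <- !is.na(rsa)
  chain_letter <- substr(chain_id, nchar(chain_id), nchar(chain_id))
  three <- ifelse(aa %in% names(AA_THREE), AA_THREE[aa], "UNK")
  c(sprintf("REM  RES _ %s synthetic relative accessibilities", chain_id),
    "REM                ABS   REL    ABS   REL    ABS   REL    ABS   REL",
    sprintf("RES %3s %s%4d  %6.2f %6.2f %6.2f %6.2f %6.2f %6.2f %6.2f %6.2f",
            three[keep], chain_letter, which(keep),
            rsa[keep], rsa[keep], rsa[keep], rsa[keep],
            rsa[keep], rsa[keep], rsa[keep], rsa[keep]),
    "END  Absolute sums over accessible surface")
}

#' Write a complete synthetic fixture directory
#'
#' Materializes a [simulate_records()] run as the on-disk formats the
#' pipeline consumes: a FASTA file of query chains, the tabular alignment
#' file, one single-chain \code{.rsa} file per chain (plus a
#' complex-context \code{_complex.rsa} file for oligomer chains), a
#' disorder-propensity CSV, the full residue truth table, and a manifest
#' JSON recording the configuration and the generating coefficients.  All
#' files are synthetic and deterministic in the seed.
#'
#' @param config A [fixture_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the [simulate_records()] result.
#' @export
simulate_fixture <- function(config = fixture_config(), dir) {
  sim <- simulate_records(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- sim$records
  ## FASTA
  fa <- unlist(lapply(names(sim$sequences), function(id)
    c(paste0(">", id), paste(sim$sequences[[id]], collapse = ""))))
  writeLines(fa, file.path(dir, "chains.fasta"))
  ## alignment table
  utils::write.table(sim$hits, file.path(dir, "alignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  ## per-chain .rsa files
  for (id in names(sim$sequences)) {
    cr <- rec[rec$chain_id == id, , drop = FALSE]
    writeLines(format_rsa_lines(id, cr$aa, cr$rsa),
               file.path(dir, paste0(id, ".rsa")))
    if (any(cr$oligomer, na.rm = TRUE))
      writeLines(format_rsa_lines(id, cr$aa, cr$rsa_complex),
                 file.path(dir, paste0(id, "_complex.rsa")))
  }
  ## disorder propensities
  utils::write.csv(rec[, c("chain_id", "position", "lgdp")],
                   file.path(dir, "lgdp.csv"), row.names = FALSE,
                   quote = FALSE)
  ## truth table and manifest
  write_residue_csv(rec, file.path(dir, "residues.csv"))
  manifest <- sim$config
  tm <- sim$config$true_model
  manifest$true_model <- list(descriptors = tm$spec$descriptors,
                              coefficients = as.list(tm$coefficients))
  class(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(sim)
}
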