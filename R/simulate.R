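# Synthetic cohort / cell-line / knock-down generators with a ground-truth
# ledger, emulating the statistical structure the discovery pipeline assumes:
# Gaussian background expression, per-gene median-centering, independent
# per-(sample, gene) driver mutations, a planted CRF->module shift applied
# before centering, optional mutually exclusive alteration structure, and
# matched cell-line / knock-down panels.

#' Derive independent component seeds from one master seed
#'
#' The splitting rule: seed the base generator with the master seed and draw
#' `n` integers uniformly below 2^31 - 1.  Each component of a simulated
#' bundle is seeded from its own slot so components are independently
#' reproducible.
#'
#' @param seed Master integer seed.
#' @param n Number of component seeds.
#' @return Integer vector of length `n`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

default_driver_table <- function(focal_crf = "CRF1") {
  data.frame(
    gene = c(focal_crf, "CRF2", "CRF3",
             paste0("DRV", 1:8)),
    prob = c(0.30, 0.05, 0.05, rep(0.08, 8)),
    is_crf = c(TRUE, TRUE, TRUE, rep(FALSE, 8)),
    stringsAsFactors = FALSE)
}

#' Simulate a paired mutation/expression tumor cohort
#'
#' Background expression is i.i.d. Normal(0, `sigma`).  Samples that acquire
#' a protein-affecting mutation of the focal CRF have the planted module's
#' up-genes shifted by `+delta` and down-genes by `-delta` *before* per-gene
#' median-centering, so part of the mutated-group offset is absorbed by the
#' centering, as in real median-centered data.  Driver mutations are
#' independent Bernoulli draws per (sample, gene) at the given frequencies,
#' except an optional set of mutually exclusive genes which are drawn so that
#' at most one of them alters any sample.
#'
#' @param n_samples,n_genes Cohort dimensions (defaults 200 x 2000).
#' @param drivers Data frame with columns `gene`, `prob`, `is_crf`; defaults
#'   to one focal CRF at frequency 0.3, two other driver CRFs at 0.05 and
#'   eight non-CRF drivers at 0.08.
#' @param focal_crf The driver CRF whose mutations carry the planted effect.
#' @param k_up,k_down Planted module sizes per direction (defaults 30 + 30).
#' @param delta Planted expression shift (same units as `sigma`; default 2).
#' @param sigma Background standard deviation (default 1).
#' @param mutex_genes Optional character vector of genes given a mutually
#'   exclusive alteration pattern; frequencies taken from `drivers` (genes
#'   absent from `drivers` get `mutex_prob`).
#' @param mutex_prob Alteration frequency for `mutex_genes` not listed in
#'   `drivers` (default 0.15).
#' @param n_decoy_sets,decoy_set_size Unplanted random gene sets included in
#'   the bundled collection (defaults 20 sets of 60).
#' @param seed Master seed; the same seed reproduces the bundle bit for bit.
#' @return A `cohort_bundle`: list with `expression`, `mutations`,
#'   `registry`, `gene_sets` (list of one `gene_set_collection`), and
#'   `truth` (focal CRF, planted set name, member genes per direction,
#'   `delta`, controller gene, mutually exclusive genes).
#' @export
simulate_cohort <- function(n_samples = 200, n_genes = 2000,
                            drivers = default_driver_table(focal_crf),
                            focal_crf = "CRF1",
                            k_up = 30, k_down = 30,
                            delta = 2, sigma = 1,
                            mutex_genes = NULL, mutex_prob = 0.15,
                            n_decoy_sets = 20, decoy_set_size = 60,
                            seed = 1L) {
  stop_if(k_up + k_down > n_genes, "k_up + k_down must not exceed n_genes")
  stop_if(!focal_crf %in% drivers$gene, "focal_crf must appear in drivers")
  stop_if(any(drivers$prob < 0 | drivers$prob > 1),
          "mutation probabilities must lie in [0, 1]")
  seeds <- split_seed(seed, 4)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)

  genes <- sprintf("G%05d", seq_len(n_genes))
  samples <- sprintf("S%04d", seq_len(n_samples))

  # mutations: independent Bernoulli per (sample, driver gene)
  set.seed(seeds[1])
  rec_s <- character(); rec_g <- character()
  mx <- intersect(mutex_genes, drivers$gene)
  indep <- drivers[!(drivers$gene %in% mutex_genes), , drop = FALSE]
  for (i in seq_len(nrow(indep))) {
    hit <- which(stats::runif(n_samples) < indep$prob[i])
    rec_s <- c(rec_s, samples[hit])
    rec_g <- c(rec_g, rep(indep$gene[i], length(hit)))
  }
  if (length(mutex_genes) > 0) {
    probs <- stats::setNames(rep(mutex_prob, length(mutex_genes)), mutex_genes)
    probs[mx] <- drivers$prob[match(mx, drivers$gene)]
    stop_if(sum(probs) > 1,
            "infeasible exclusivity: mutually exclusive frequencies sum above 1")
    # one multinomial draw per sample: gene i w.p. probs[i], none otherwise
    pick <- apply(stats::rmultinom(n_samples, 1, c(probs, 1 - sum(probs))),
                  2, which.max)
    hit <- which(pick <= length(mutex_genes))
    rec_s <- c(rec_s, samples[hit])
    rec_g <- c(rec_g, mutex_genes[pick[hit]])
  }
  mutations <- mutation_catalog(rec_s, rec_g, rep("missense", length(rec_s)))

  # planted module membership
  set.seed(seeds[2])
  planted <- sample(genes, k_up + k_down)
  up_genes <- sort(planted[seq_len(k_up)])
  down_genes <- sort(planted[k_up + seq_len(k_down)])

  # expression: background noise + planted shift in focal-mutated samples,
  # then per-gene median-centering
  set.seed(seeds[3])
  expr <- matrix(stats::rnorm(n_genes * n_samples, 0, sigma),
                 n_genes, n_samples, dimnames = list(genes, samples))
  focal_mut <- samples %in% mutations$sample[
    mutations$gene == focal_crf & mutations$effect == "PAM"]
  if (any(focal_mut)) {
    expr[up_genes, focal_mut] <- expr[up_genes, focal_mut] + delta
    expr[down_genes, focal_mut] <- expr[down_genes, focal_mut] - delta
  }
  expr <- expr - apply(expr, 1, stats::median)

  # gene-set collection: the planted set plus random decoys
  set.seed(seeds[4])
  sets <- list(PLANTED_M1 = sort(c(up_genes, down_genes)))
  if (n_decoy_sets > 0) {
    for (i in seq_len(n_decoy_sets)) {
      sets[[sprintf("DECOY_%02d", i)]] <- sort(sample(genes, decoy_set_size))
    }
  }
  controllers <- stats::setNames(paste0("TF_", names(sets)), names(sets))
  collection <- gene_set_collection("simsets", "tf_targets", sets,
                                    controllers = controllers)

  registry <- driver_registry(
    drivers$gene, is_driver = TRUE, is_crf = drivers$is_crf,
    mode = ifelse(drivers$is_crf, "LoF", "unknown"))

  structure(list(
    expression = expr,
    mutations = mutations,
    registry = registry,
    gene_sets = list(collection),
    truth = list(focal_crf = focal_crf, planted_set = "PLANTED_M1",
                 up_genes = up_genes, down_genes = down_genes,
                 delta = delta, sigma = sigma,
                 controller = controllers[["PLANTED_M1"]],
                 mutex_genes = mutex_genes,
                 focal_mutated_samples = samples[focal_mut])
  ), class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(paste0("synthetic cohort: %d genes x %d samples; focal CRF %s ",
                     "mutated in %d samples; planted module '%s' (%d up / %d down, delta = %g)\n"),
              nrow(x$expression), ncol(x$expression), x$truth$focal_crf,
              length(x$truth$focal_mutated_samples), x$truth$planted_set,
              length(x$truth$up_genes), length(x$truth$down_genes),
              x$truth$delta))
  invisible(x)
}

#' Simulate a cancer cell-line panel
#'
#' Same planted-shift contract as [simulate_cohort()], applied to the lines
#' mutated in the focal CRF; tissue labels are assigned round-robin from the
#' vocabulary.
#'
#' @param n_mut,n_wt Numbers of focal-CRF-mutated and wild-type lines.
#' @param n_genes Assayed gene universe size.
#' @param up_genes,down_genes Planted module members per direction (character
#'   vectors of gene ids `G00001`-style, or `NULL` for none).
#' @param focal_crf Focal CRF gene id.
#' @param delta,sigma Planted shift and background standard deviation.
#' @param tissues Tissue vocabulary for round-robin assignment.
#' @param include_focal_status If `FALSE`, the focal CRF is dropped from the
#'   panel's assayed mutation genes, so its mutation status is unknown (the
#'   situation in which the cell-line evidence layer returns `NA`).
#' @param seed Master seed.
#' @return A `cellline_panel`: list with `expression` (genes x lines),
#'   `mutations`, `tissue` (named character), `assayed_genes`.
#' @export
simulate_cell_lines <- function(n_mut = 10, n_wt = 10, n_genes = 2000,
                                up_genes = NULL, down_genes = NULL,
                                focal_crf = "CRF1", delta = 3, sigma = 1,
                                tissues = "tissueA",
                                include_focal_status = TRUE, seed = 1L) {
  n_lines <- n_mut + n_wt
  stop_if(n_lines < 4, "need at least 4 cell lines for a group comparison")
  seeds <- split_seed(seed, 2)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)

  genes <- sprintf("G%05d", seq_len(n_genes))
  stop_if(!all(c(up_genes, down_genes) %in% genes),
          "planted module genes must lie inside the simulated gene universe")
  lines_ <- sprintf("CL%03d", seq_len(n_lines))
  mut_lines <- lines_[seq_len(n_mut)]

  set.seed(seeds[1])
  expr <- matrix(stats::rnorm(n_genes * n_lines, 0, sigma),
                 n_genes, n_lines, dimnames = list(genes, lines_))
  if (n_mut > 0 && length(up_genes) > 0)
    expr[up_genes, mut_lines] <- expr[up_genes, mut_lines] + delta
  if (n_mut > 0 && length(down_genes) > 0)
    expr[down_genes, mut_lines] <- expr[down_genes, mut_lines] - delta
  expr <- expr - apply(expr, 1, stats::median)

  mutations <- mutation_catalog(mut_lines, rep(focal_crf, n_mut),
                                rep("missense", n_mut))
  tissue <- stats::setNames(rep(tissues, length.out = n_lines), lines_)
  assayed <- if (include_focal_status) focal_crf else character()

  structure(list(expression = expr, mutations = mutations, tissue = tissue,
                 assayed_genes = assayed,
                 truth = list(focal_crf = focal_crf, delta = delta,
                              mutated_lines = mut_lines)),
            class = "cellline_panel")
}

#' Simulate a knock-down signature catalog
#'
#' Each target gets a latent "extreme" signature of `floor(2 * q * n_universe)`
#' genes; every experiment of that target reports those genes with large
#' absolute z-values (so they fall in the tails) and Normal(0, 1) noise for
#' the rest.  A fraction `rho` of each target's signature is drawn from a
#' pool shared by all targets; with `rho = 0` the per-target signatures are
#' independent random draws, so cross-target overlaps are hypergeometric.
#'
#' @param targets Character vector of knocked-down genes.
#' @param n_experiments Experiments per target (single number or named
#'   vector).
#' @param n_universe Assayed gene universe size (default 1000).
#' @param rho Shared fraction of the extreme signature, in `[0, 1]`.
#' @param q Tail quantile the downstream extreme-gene rule will use
#'   (default 0.025); sets the latent signature size.
#' @param seed Master seed.
#' @return A `kd_catalog`: list with `universe` (gene ids) and `experiments`
#'   (named list: target -> list of named numeric z-vectors).
#' @export
simulate_kd_experiments <- function(targets, n_experiments = 2,
                                    n_universe = 1000, rho = 0, q = 0.025,
                                    seed = 1L) {
  stop_if(rho < 0 || rho > 1, "rho must lie in [0, 1]")
  stop_if(length(targets) < 1, "need at least one target")
  if (length(n_experiments) == 1)
    n_experiments <- stats::setNames(rep(n_experiments, length(targets)), targets)
  seeds <- split_seed(seed, 2)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)

  genes <- sprintf("G%05d", seq_len(n_universe))
  m <- floor(2 * q * n_universe)          # latent signature size per target
  s <- floor(rho * m)                     # genes shared across targets

  set.seed(seeds[1])
  shared <- if (s > 0) sample(genes, s) else character()
  signatures <- lapply(targets, function(t) {
    own <- sample(setdiff(genes, shared), m - s)
    sig <- c(shared, own)
    # balanced signs: exactly half the signature in each tail, so every
    # experiment's tails are filled by signature genes
    stats::setNames(sample(rep(c(-1, 1), length.out = length(sig))), sig)
  })
  names(signatures) <- targets

  set.seed(seeds[2])
  experiments <- lapply(targets, function(t) {
    sig <- signatures[[t]]
    lapply(seq_len(n_experiments[[t]]), function(e) {
      z <- stats::setNames(stats::rnorm(n_universe), genes)
      if (length(sig) > 0)
        z[names(sig)] <- sig * (6 + abs(stats::rnorm(length(sig), 0, 0.25)))
      z
    })
  })
  names(experiments) <- targets
  structure(list(universe = genes, experiments = experiments,
                 truth = list(signatures = signatures, rho = rho)),
            class = "kd_catalog")
}

#' Write a synthetic cohort bundle to disk
#'
#' Emits the full on-disk bundle in the package's standard formats:
#' `expression.tsv`, `mutations.tsv`, `registry.tsv`, one `<collection>.gmt`
#' per collection, and `truth.tsv` (the ground-truth ledger).
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    mutations = file.path(dir, "mutations.tsv"),
    registry = file.path(dir, "registry.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_expression(bundle$expression, paths["expression"])
  utils::write.table(as.data.frame(bundle$mutations), paths["mutations"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(unclass(bundle$registry)), paths["registry"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (col in bundle$gene_sets) {
    p <- file.path(dir, paste0(col$name, ".gmt"))
    write_gene_sets(col, p)
    paths[paste0("gmt_", col$name)] <- p
  }
  tr <- bundle$truth
  truth_df <- data.frame(
    key = c("focal_crf", "planted_set", "delta", "sigma", "controller",
            "up_genes", "down_genes", "mutex_genes"),
    value = c(tr$focal_crf, tr$planted_set, tr$delta, tr$sigma, tr$controller,
              paste(tr$up_genes, collapse = ","),
              paste(tr$down_genes, collapse = ","),
              paste(tr$mutex_genes, collapse = ",")),
    stringsAsFactors = FALSE)
  utils::write.table(truth_df, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
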