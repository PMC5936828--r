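# Seeded synthetic datasets emulating the study conditions: mixtures of
# paucimannose / high-mannose structures (Man-2..Man-6 cores) with
# galactosylated core fucose (forms a-f) and selective O-methylation, and
# the MALDI MS1 / MS-MS / treatment-pair / PMAA datasets derived from them.

#' Specify a synthetic glycan mixture
#'
#' The default roster is the structural grammar of this glycome: Man-2 to
#' Man-6 cores, each without core modification or with an alpha1-6 core
#' fucose extended by 0-5 galactoses (forms a-f; first Gal beta1-4
#' unmethylated, further Gals methylated), crossed with 0-3 O-methyls on
#' terminal mannoses. Abundances are Dirichlet-distributed with
#' concentration weights elevated for the di/tri-galactosylated forms c and
#' d, the predominant glycomers in this system.
#'
#' @param seed integer RNG seed recorded in the mixture.
#' @param derivatization derivatization of all structures.
#' @param man_range mannose counts of the cores (default 2:6).
#' @param include_unfucosylated include the plain paucimannose/high-mannose
#'   cores.
#' @param forms core-fucose extension forms included (letters a-f).
#' @param max_man_me cap on terminal-mannose methyls per structure.
#' @param form_alpha named Dirichlet concentration weights per form
#'   (`none` = unfucosylated).
#' @param noise list: `mz_sd` (Gaussian m/z jitter sd, Da), `int_sdlog`
#'   (lognormal intensity sd), `spurious_rate` (expected spurious peaks per
#'   spectrum), `spurious_frac` (their intensity as a fraction of the base
#'   peak).
#' @return a list of class `mixture_spec`.
#' @export
mixture_spec <- function(seed = 1L, derivatization = "permethylated",
                         man_range = 2:6, include_unfucosylated = TRUE,
                         forms = letters[1:6], max_man_me = 3L,
                         form_alpha = c(none = 3, a = 1, b = 2, c = 4,
                                        d = 4, e = 1, f = 0.5),
                         noise = list(mz_sd = 0.02, int_sdlog = 0.1,
                                      spurious_rate = 5,
                                      spurious_frac = 0.01)) {
  stopifnot(all(man_range %in% 1:6), all(forms %in% letters[1:6]))
  structure(list(seed = as.integer(seed),
                 derivatization = normalize_derivatization(derivatization),
                 man_range = man_range,
                 include_unfucosylated = isTRUE(include_unfucosylated),
                 forms = forms, max_man_me = as.integer(max_man_me),
                 form_alpha = form_alpha, noise = noise),
            class = "mixture_spec")
}

n_terminal_man <- function(man) {
  arms <- .man_arms[[as.character(man)]]
  if (length(arms) == 0L) return(1L)  # the beta-Man itself is terminal
  length(arms)
}

#' Generate a ground-truth structure mixture
#'
#' Builds the roster defined by a [mixture_spec()] and draws Dirichlet
#' abundances (via normalized Gamma draws) under the spec's seed;
#' reproducible given the seed.
#'
#' @param spec a [mixture_spec()].
#' @return list of class `glycan_mixture`: `structures` (list of
#'   [glycan_tree()]), `abundances` (sums to 1), `table` (data.frame of
#'   `man`, `form`, `man_me`, `mz`, `structure`), `spec`.
#' @export
#' @examples
#' mx <- generate_mixture(mixture_spec(seed = 1))
#' length(mx$structures)  # > 60 glycoforms
generate_mixture <- function(spec = mixture_spec()) {
  stopifnot(inherits(spec, "mixture_spec"))
  set.seed(spec$seed)
  structures <- list()
  rows <- list()
  alpha <- numeric()
  forms <- c(if (spec$include_unfucosylated) "none", spec$forms)
  for (man in spec$man_range) {
    for (form in forms) {
      gal <- if (form == "none") 0L else glycomer_form(form)
      for (me in 0:min(spec$max_man_me, n_terminal_man(man))) {
        tr <- build_nglycan(man = man, fucosylated = form != "none",
                            core_gal = gal, man_me = me,
                            derivatization = spec$derivatization)
        structures[[length(structures) + 1L]] <- tr
        rows[[length(rows) + 1L]] <-
          data.frame(man = man, form = form, man_me = me,
                     mz = tree_mass(tr),
                     structure = serialize_structure(tr),
                     stringsAsFactors = FALSE)
        a <- spec$form_alpha[[form]]
        if (is.null(a) || is.na(a)) a <- 1
        alpha <- c(alpha, a)
      }
    }
  }
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  abund <- g / sum(g)
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tab$abundance <- abund
  structure(list(structures = structures, abundances = abund, table = tab,
                 spec = spec),
            class = "glycan_mixture")
}

as_mixture <- function(x) {
  if (inherits(x, "glycan_mixture")) return(x)
  if (is.list(x) && !is.null(x$structures)) {
    ab <- x$abundances %||% rep(1 / length(x$structures),
                                length(x$structures))
    return(structure(list(structures = x$structures,
                          abundances = ab / sum(ab)), class = "glycan_mixture"))
  }
  stop("not a glycan mixture", call. = FALSE)
}

#' Synthesize an MS1 peak list from a mixture
#'
#' One peak per distinct theoretical m/z (isobars sum their abundances);
#' intensities are abundance times a lognormal factor scaled to 1e4, m/z
#' values carry Gaussian jitter, and a Poisson number of spurious peaks at
#' a fraction of the base peak is added. With all noise parameters zero the
#' peak m/z equal the theoretical masses exactly.
#'
#' @param mixture a `glycan_mixture` (or list with `structures`,
#'   `abundances`).
#' @param noise noise list as in [mixture_spec()]; defaults to the
#'   mixture's spec, else noiseless.
#' @param seed optional seed applied before sampling.
#' @return a [peak_list()] (MS level 1).
#' @export
synthesize_ms1 <- function(mixture, noise = NULL, seed = NULL) {
  mixture <- as_mixture(mixture)
  noise <- noise %||% mixture$spec$noise %||%
    list(mz_sd = 0, int_sdlog = 0, spurious_rate = 0, spurious_frac = 0)
  if (!is.null(seed)) set.seed(seed)
  deriv <- mixture$structures[[1]]$derivatization
  mzs <- vapply(mixture$structures, tree_mass, numeric(1))
  key <- sprintf("%.5f", mzs)
  ab <- tapply(mixture$abundances, key, sum)
  mz <- as.numeric(names(ab))
  ord <- order(mz)
  mz <- mz[ord]; ab <- as.numeric(ab)[ord]
  int <- ab * 1e4 * stats::rlnorm(length(ab), 0, noise$int_sdlog %||% 0)
  mz <- mz + stats::rnorm(length(mz), 0, noise$mz_sd %||% 0)
  n_sp <- if ((noise$spurious_rate %||% 0) > 0)
    stats::rpois(1, noise$spurious_rate) else 0L
  if (n_sp > 0L && length(mz)) {
    mz <- c(mz, stats::runif(n_sp, min(mz) - 50, max(mz) + 50))
    int <- c(int, rep(max(int) * (noise$spurious_frac %||% 0.01), n_sp))
  }
  peak_list(mz, int, ms_level = 1, derivatization = deriv)
}

#' Form weights of a mixture within one F1HnN2 parent mass
#'
#' @param mixture a `glycan_mixture` with a `table` component.
#' @param parent_comp parent composition (object or `"F1HnN2"` string).
#' @return named numeric (form letter -> abundance share, sums to 1).
#' @export
mixture_form_weights <- function(mixture, parent_comp) {
  if (is.character(parent_comp)) parent_comp <- parse_fhn(parent_comp)
  stopifnot(inherits(mixture, "glycan_mixture"), !is.null(mixture$table))
  tab <- mixture$table
  sel <- vapply(seq_len(nrow(tab)), function(i) {
    comp <- tree_composition(mixture$structures[[i]])
    comp_equal(comp, parent_comp, ignore_me = TRUE) && tab$form[i] != "none"
  }, logical(1))
  if (!any(sel)) return(stats::setNames(numeric(), character()))
  w <- tapply(tab$abundance[sel], tab$form[sel], sum)
  w <- w / sum(w)
  stats::setNames(as.numeric(w), names(w))
}

#' Synthesize an MS/MS spectrum of one F1HnN2 parent
#'
#' Fragment peaks are the chitobiose B/Y pairs of each glycomer form,
#' weighted by the form's abundance share within the parent mass, with the
#' same noise model as [synthesize_ms1()].
#'
#' @param x either a `glycan_mixture` (form weights derived with
#'   [mixture_form_weights()]) or a named numeric of form weights
#'   (`c(b = 0.25, c = 0.75)`).
#' @param parent_comp parent composition (object or `"F1HnN2"` string),
#'   permethylated.
#' @param noise noise list (see [mixture_spec()]); default noiseless.
#' @param seed optional seed applied before sampling.
#' @return a [peak_list()] with `ms_level = 2` and the parent m/z set.
#' @export
#' @examples
#' sp <- synthesize_msms(c(b = 0.25, c = 0.75), "F1H5N2")
#' call_glycomers(sp, "F1H5N2")
synthesize_msms <- function(x, parent_comp, noise = NULL, seed = NULL) {
  if (is.character(parent_comp))
    parent_comp <- parse_fhn(parent_comp, "permethylated")
  weights <- if (inherits(x, "glycan_mixture"))
    mixture_form_weights(x, parent_comp) else x
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  noise <- noise %||% list(mz_sd = 0, int_sdlog = 0, spurious_rate = 0,
                           spurious_frac = 0)
  if (!is.null(seed)) set.seed(seed)
  cand <- candidate_pairs(parent_comp)
  cand <- cand[cand$form %in% names(weights), , drop = FALSE]
  if (nrow(cand) == 0L)
    return(peak_list(ms_level = 2,
                     parent_mz = composition_mass(parent_comp)))
  w <- as.numeric(weights[cand$form])
  w <- w / sum(w)
  mz <- c(cand$B_mz, cand$Y_mz)
  int <- rep(w, 2L) * 1e4 *
    stats::rlnorm(2L * length(w), 0, noise$int_sdlog %||% 0)
  mz <- mz + stats::rnorm(length(mz), 0, noise$mz_sd %||% 0)
  n_sp <- if ((noise$spurious_rate %||% 0) > 0)
    stats::rpois(1, noise$spurious_rate) else 0L
  if (n_sp > 0L) {
    mz <- c(mz, stats::runif(n_sp, 200, composition_mass(parent_comp)))
    int <- c(int, rep(max(int) * (noise$spurious_frac %||% 0.01), n_sp))
  }
  peak_list(mz, int, ms_level = 2, parent_mz = composition_mass(parent_comp))
}

#' Synthesize a before/after treatment spectrum pair
#'
#' @param mixture a `glycan_mixture`.
#' @param spec a [treatment_spec()] or built-in name.
#' @param noise noise list; default noiseless (so shifts are exact).
#' @param seed optional seed (the before and after draws consume one
#'   stream).
#' @return list with `before`, `after` ([peak_list()]s) and `shift`
#'   (the [predict_shift()] report).
#' @export
synthesize_treatment_pair <- function(mixture, spec, noise = NULL,
                                      seed = NULL) {
  mixture <- as_mixture(mixture)
  if (!is.null(seed)) set.seed(seed)
  if (is.character(spec)) spec <- builtin_treatments(spec)
  before <- synthesize_ms1(mixture, noise = noise)
  treated <- mixture
  treated$structures <- lapply(mixture$structures, apply_treatment,
                               spec = spec)
  after <- synthesize_ms1(treated, noise = noise)
  list(before = before, after = after,
       shift = predict_shift(mixture$structures, spec,
                             abundances = mixture$abundances))
}

#' Synthesize PMAA records from a mixture
#'
#' Linkage-category counts are taken directly from the ground-truth trees
#' (see [tree_linkage_counts()]), weighted by structure abundance; each
#' category present in the reference table yields one record carrying the
#' reference retention time and signature-ion set. Categories without a
#' reference row (notably terminal fucose, undetected in this system) are
#' returned in the `unrepresented` attribute.
#'
#' @param mixture a `glycan_mixture`.
#' @param scale abundance scale factor (default 100).
#' @return data.frame (`rt`, `ions`, `abundance`, `linkage`,
#'   `true_linkage`), with attribute `unrepresented`; `linkage` starts equal
#'   to the truth and is overwritten by [assign_linkages()] round-trips.
#' @export
synthesize_pmaa <- function(mixture, scale = 100) {
  mixture <- as_mixture(mixture)
  if (length(mixture$structures) == 0L) {
    out <- data.frame(rt = numeric(), ions = character(),
                      abundance = numeric(), linkage = character(),
                      true_linkage = character(), stringsAsFactors = FALSE)
    attr(out, "unrepresented") <- character()
    return(out)
  }
  agg <- new.env(parent = emptyenv())
  for (i in seq_along(mixture$structures)) {
    cnt <- tree_linkage_counts(mixture$structures[[i]])
    for (cat in names(cnt)) {
      prev <- mget(cat, envir = agg, ifnotfound = 0)[[1]]
      assign(cat, prev + cnt[[cat]] * mixture$abundances[i], envir = agg)
    }
  }
  cats <- ls(agg)
  ref <- pmaa_reference()
  known <- cats[cats %in% ref$linkage]
  idx <- match(known, ref$linkage)
  out <- data.frame(rt = ref$rt[idx], ions = ref$ions[idx],
                    abundance = scale *
                      vapply(known, function(cat) get(cat, envir = agg),
                             numeric(1)),
                    linkage = known, true_linkage = known,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rt), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unrepresented") <- setdiff(cats, ref$linkage)
  out
}
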