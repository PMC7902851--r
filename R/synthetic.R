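#' Specification for a synthetic jaw-ecomorphology dataset
#'
#' Defines the conditions the generator emulates: a training set of extant
#' taxa in four diet classes (default class sizes 8 herbivores, 16
#' carnivores, 13 insectivores, 33 omnivores), a set of fossil taxa entering
#' the pipeline unlabelled, a fixed landmark regimen (6 fixed + 58 sliding
#' semi-landmarks), diet-dependent template deformations, Brownian
#' phylogenetic noise on the deformation coefficients, digitization noise on
#' the landmarks, and diet-dependent moment-arm means.
#'
#' Default magnitudes: the template jaw is ~10 units long; `sigma_obs` is
#' per-coordinate digitization noise (0.04 units); `delta` is the class
#' shape-effect size in template-deformation units (0.2 = 5 `sigma_obs`);
#' `sigma2_bm` is the Brownian rate per Myr on the deformation coefficients
#' (1e-5, giving a deviate SD of ~0.05 over a 250-Myr root-to-tip path).
#'
#' @param n_training named integer vector of training taxa per diet class.
#' @param n_fossil number of fossil (predict) taxa; their true diets are
#'   drawn from the three non-omnivore classes, as in Mesozoic samples.
#' @param k_fixed,k_sliding landmark regimen (6 + 58 by default).
#' @param delta class shape-effect size, template-deformation units.
#' @param sigma2_bm Brownian rate of the deformation coefficients, per Myr.
#' @param sigma_obs per-coordinate digitization noise SD.
#' @param fad_window fossil first-appearance window in Ma.
#' @param ma_means,ma_sds per-class moment-arm means/SDs; see
#'   [default_ma_means()].
#' @param seed mandatory integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_training = c(herbivore = 8, carnivore = 16,
                                          insectivore = 13, omnivore = 33),
                           n_fossil = 45,
                           k_fixed = 6, k_sliding = 58,
                           delta = 0.2,
                           sigma2_bm = 1e-5,
                           sigma_obs = 0.04,
                           fad_window = c(66, 201),
                           ma_means = default_ma_means(),
                           ma_sds = default_ma_sds(),
                           seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (delta < 0) stop("delta must be >= 0")
  if (sigma2_bm < 0 || sigma_obs < 0) stop("noise SDs must be >= 0")
  diets <- c("herbivore", "carnivore", "insectivore", "omnivore")
  if (!setequal(names(n_training), diets))
    stop("n_training must name the four diet classes")
  structure(
    list(n_training = n_training[diets], n_fossil = n_fossil,
         k_fixed = k_fixed, k_sliding = k_sliding, delta = delta,
         sigma2_bm = sigma2_bm, sigma_obs = sigma_obs,
         fad_window = fad_window, ma_means = ma_means, ma_sds = ma_sds,
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_ma_means <- function() {
  # qualitative diet structure: herbivores high MAM and MAT; carnivores low
  # MAM, high MAT; insectivores low-to-medium MAM and MAT; omnivores between
  list(
    herbivore   = c(inlever_masseter = 3.4, inlever_temporalis = 5.0,
                    outlever_tip = 10, outlever_m1 = 6),
    carnivore   = c(inlever_masseter = 2.0, inlever_temporalis = 4.6,
                    outlever_tip = 10, outlever_m1 = 6),
    insectivore = c(inlever_masseter = 2.2, inlever_temporalis = 3.4,
                    outlever_tip = 10, outlever_m1 = 6),
    omnivore    = c(inlever_masseter = 2.8, inlever_temporalis = 4.2,
                    outlever_tip = 10, outlever_m1 = 6))
}

#' @rdname synthetic_spec
#' @export
default_ma_sds <- function() {
  c(inlever_masseter = 0.25, inlever_temporalis = 0.25,
    outlever_tip = 0.5, outlever_m1 = 0.35)
}

#' Template jaw and diet deformation fields
#'
#' A schematic mandible in lateral view: horizontal ramus running to the
#' anterior tip, ascending ramus with coronoid process, condyle and angular
#' region. Returns the 6 fixed landmarks (anterior tip, coronoid apex,
#' condyle, angular process, ventral-border midpoint, m1 position), the 58
#' sliding semi-landmarks distributed along four outline curves, and two
#' unit-RMS deformation fields: jaw elongation (positive = longer jaw) and
#' ascending-ramus height (positive = taller ramus).
#'
#' @param k_sliding number of sliding semi-landmarks (default 58).
#' @return list with `coords` (k x 2), `fixed_idx`, `curves`, `fields`
#'   (k x 2 x 2 array).
#' @export
jaw_template <- function(k_sliding = 58) {
  # fixed landmarks
  tip      <- c(10.0, 0.8)   # 1 anterior tip of the jaw
  coronoid <- c(1.2, 3.2)    # 2 coronoid apex
  condyle  <- c(0.0, 1.0)    # 3 condyle (jaw joint)
  angle    <- c(0.6, -0.8)   # 4 angular region
  ventral  <- c(5.5, -0.4)   # 5 ventral border midpoint
  m1       <- c(6.0, 1.1)    # 6 first lower molar position
  fixed <- rbind(tip, coronoid, condyle, angle, ventral, m1)

  # sliders along four outline curves (counts sum to k_sliding)
  base <- k_sliding %/% 4
  n1 <- base + (k_sliding - 4 * base)      # dorsal: tip -> m1
  n2 <- base                               # dorsal posterior: m1 -> coronoid
  n3 <- base                               # posterior: coronoid -> condyle -> angle
  n4 <- base                               # ventral: angle -> ventral -> tip
  bow <- function(a, b, n, sag) {
    # quadratic arc from a to b with perpendicular sag, n interior points
    t <- seq_len(n) / (n + 1)
    p <- outer(1 - t, a) + outer(t, b)
    d <- b - a
    nrm <- c(-d[2], d[1]) / sqrt(sum(d^2))
    p + outer(4 * t * (1 - t) * sag, nrm)
  }
  s1 <- bow(tip, m1, n1, 0.15)
  s2 <- bow(m1, coronoid, n2, 0.25)
  half <- n3 %/% 2
  s3 <- rbind(bow(coronoid, condyle, half, 0.3),
              bow(condyle, angle, n3 - half, 0.3))
  s4 <- rbind(bow(angle, ventral, n4 %/% 2, -0.2),
              bow(ventral, tip, n4 - n4 %/% 2, -0.2))
  coords <- rbind(fixed, s1, s2, s3, s4)
  rownames(coords) <- NULL
  k <- nrow(coords)
  i1 <- 6 + seq_len(n1)
  i2 <- 6 + n1 + seq_len(n2)
  i3 <- 6 + n1 + n2 + seq_len(n3)
  i4 <- 6 + n1 + n2 + n3 + seq_len(n4)
  curves <- list(c(1L, i1, 6L),            # tip .. m1 (dorsal)
                 c(6L, i2, 2L),            # m1 .. coronoid
                 c(2L, i3, 4L),            # coronoid .. angle (via condyle side)
                 c(4L, i4, 1L))            # angle .. tip (ventral)

  # deformation fields, unit RMS displacement
  x0 <- condyle[1]
  span <- max(coords[, 1]) - x0
  f_len <- cbind((coords[, 1] - x0) / span, 0)
  f_len <- f_len / sqrt(mean(rowSums(f_len^2)))
  w <- exp(-((coords[, 1] - coronoid[1])^2) / (2 * 1.6^2)) *
    pmax(coords[, 2], 0) / coronoid[2]
  f_ram <- cbind(0, w)
  f_ram <- f_ram / sqrt(mean(rowSums(f_ram^2)))
  fields <- array(c(f_len, f_ram), c(k, 2, 2),
                  dimnames = list(NULL, NULL, c("length", "ramus")))
  list(coords = coords, fixed_idx = 1:6, curves = curves, fields = fields)
}

# class means in deformation-coefficient space (length, ramus), in units of
# delta; encodes: herbivores short jaws/tall rami, insectivores long
# jaws/short rami, carnivores intermediate-short jaws, omnivores central
class_deformation <- function(delta) {
  rbind(herbivore   = c(-1, 1) * delta,
        carnivore   = c(-0.5, 0.25) * delta,
        insectivore = c(1, -1) * delta,
        omnivore    = c(0, 0))
}

#' Random time tree for synthetic datasets
#'
#' Birth-death-shaped random topology (via `ape::rtree`) with node ages
#' assigned top-down so that every branch is strictly positive: extant tips
#' at 0 Ma, fossil tips at first-appearance dates drawn uniformly from
#' `fad_window`. Also returns the un-scaled cladogram and FAD table so the
#' "equal" time-scaling can be exercised against the known true tree.
#'
#' @param n_tips total tips (>= 3).
#' @param seed integer seed.
#' @param n_fossil how many tips are fossils (default 0: ultrametric tree).
#' @param fad_window FAD window in Ma for fossil tips.
#' @param tip_labels optional tip names (first `n_fossil` become fossils).
#' @return list with `time_tree`, `cladogram` (no branch lengths), `fads`
#'   (named FADs), `is_fossil` (named logical).
#' @export
make_tree <- function(n_tips, seed, n_fossil = 0,
                      fad_window = c(66, 201), tip_labels = NULL) {
  if (n_tips < 3L) stop("need at least 3 tips")
  if (n_fossil > n_tips) stop("n_fossil exceeds n_tips")
  with_seed(derive_seed(seed, 101), {
    phy <- ape::rtree(n_tips, br = NULL)
    if (!is.null(tip_labels)) {
      stopifnot(length(tip_labels) == n_tips)
      phy$tip.label <- tip_labels[as.integer(sub("^t", "", phy$tip.label))]
    }
    is_fossil <- stats::setNames(rep(FALSE, n_tips), phy$tip.label)
    if (n_fossil > 0) {
      chosen <- if (is.null(tip_labels)) sample(phy$tip.label, n_fossil)
                else tip_labels[seq_len(n_fossil)]
      is_fossil[chosen] <- TRUE
    }
    fads <- stats::setNames(rep(0, n_tips), phy$tip.label)
    fads[is_fossil] <- stats::runif(sum(is_fossil),
                                    fad_window[1], fad_window[2])
    phy <- stats::reorder(phy, "cladewise")
    ntip <- n_tips
    root <- ntip + 1L
    ages <- numeric(ntip + phy$Nnode)
    ages[seq_len(ntip)] <- fads[phy$tip.label]
    for (e in rev(seq_len(nrow(phy$edge))))
      ages[phy$edge[e, 1]] <- max(ages[phy$edge[e, 1]], ages[phy$edge[e, 2]])
    ages[root] <- ages[root] + 25 + 10 * stats::runif(1)
    # preorder: place each internal node strictly between its parent and
    # its oldest descendant
    for (e in seq_len(nrow(phy$edge))) {
      ch <- phy$edge[e, 2]
      if (ch > ntip) {
        p <- phy$edge[e, 1]
        lower <- ages[ch]          # max descendant tip age, from postorder
        upper <- ages[p]
        ages[ch] <- lower + (upper - lower) * stats::runif(1, 0.35, 0.85)
      }
    }
    phy$edge.length <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
    tt <- structure(
      list(phy = phy, node_ages = ages,
           tip_ages = stats::setNames(ages[seq_len(ntip)], phy$tip.label),
           root_age = ages[root], root_extended = 0),
      class = "time_tree")
    clad <- phy
    clad$edge.length <- NULL
    list(time_tree = tt, cladogram = clad, fads = fads,
         is_fossil = is_fossil)
  })
}

#' Simulate diet-structured jaw landmark configurations
#'
#' Per taxon, the shape is the template plus the taxon's class deformation
#' (in the length/ramus coefficient space), plus a Brownian deviate of the
#' coefficients along the tree (covariance `sigma2_bm * C`), plus iid
#' digitization noise on every coordinate; the configuration is finally hit
#' with a random similarity transform (rotation, scale, translation) so the
#' superimposition has work to do.
#'
#' @param spec a [synthetic_spec()].
#' @param tree a `time_tree` whose tips are the taxa to simulate.
#' @param labels named character vector: true diet per tip.
#' @return list with `configs` (list of `landmark_config`) and
#'   `ground_truth` (data frame: taxon, diet, the two true deformation
#'   coefficients including the Brownian part).
#' @export
simulate_jaws <- function(spec, tree, labels) {
  if (spec$delta < 0) stop("delta must be >= 0")
  tmpl <- jaw_template(spec$k_sliding)
  taxa <- as_phylo(tree)$tip.label
  if (!all(taxa %in% names(labels))) stop("labels must cover every tip")
  defo <- class_deformation(spec$delta)
  base_coef <- defo[labels[taxa], , drop = FALSE]
  if (spec$sigma2_bm > 0) {
    C <- brownian_cov(tree)$C[taxa, taxa]
    L <- t(chol(spec$sigma2_bm * C))
    bm <- with_seed(derive_seed(spec$seed, 202), {
      L %*% matrix(stats::rnorm(2 * length(taxa)), ncol = 2)
    })
  } else bm <- matrix(0, length(taxa), 2)
  coef <- base_coef + bm
  configs <- vector("list", length(taxa))
  k <- nrow(tmpl$coords)
  for (i in seq_along(taxa)) {
    shape <- tmpl$coords +
      coef[i, 1] * tmpl$fields[, , "length"] +
      coef[i, 2] * tmpl$fields[, , "ramus"]
    configs[[i]] <- with_seed(derive_seed(spec$seed, 303, i), {
      shape <- shape + matrix(stats::rnorm(2 * k, sd = spec$sigma_obs), k, 2)
      th <- stats::runif(1, 0, 2 * pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      sc <- exp(stats::runif(1, -0.5, 0.7))
      shift <- stats::runif(2, -5, 5)
      landmark_config(taxa[i], sweep(sc * shape %*% R, 2L, -shift),
                      tmpl$fixed_idx, tmpl$curves)
    })
  }
  list(configs = configs,
       ground_truth = data.frame(taxon_id = taxa, diet = unname(labels[taxa]),
                                 coef_length = coef[, 1], coef_ramus = coef[, 2],
                                 stringsAsFactors = FALSE))
}

#' Simulate diet-structured moment arms
#'
#' Gaussian moment arms around diet-class means, resampled per taxon until
#' the moment-arm invariants hold (all lengths positive, tip out-lever not
#' shorter than the m1 out-lever).
#'
#' @param spec a [synthetic_spec()].
#' @param labels named character vector of true diets.
#' @return moment-arm data frame (see [validate_moment_arms()]).
#' @export
simulate_moment_arms <- function(spec, labels) {
  cols <- c("inlever_masseter", "inlever_temporalis",
            "outlever_tip", "outlever_m1")
  for (cl in unique(labels))
    if (any(spec$ma_means[[cl]] <= 0))
      stop("impossible spec: non-positive mean arm for class ", cl)
  rows <- lapply(seq_along(labels), function(i) {
    mu <- spec$ma_means[[labels[i]]][cols]
    with_seed(derive_seed(spec$seed, 404, i), {
      repeat {
        v <- stats::rnorm(4, mu, spec$ma_sds[cols])
        if (all(v > 0) && v[3] >= v[4]) break
      }
      stats::setNames(as.list(v), cols)
    })
  })
  arms <- cbind(data.frame(taxon_id = names(labels),
                           stringsAsFactors = FALSE),
                do.call(rbind, lapply(rows, as.data.frame)))
  rownames(arms) <- NULL
  validate_moment_arms(arms)
  arms
}

#' Simulate two-class traits with Brownian phylogenetic noise
#'
#' Trait matrix for lambda-recovery experiments: class means separated by
#' `delta` along a fixed direction, Brownian noise with rate `sigma2_bm`
#' along the tree, and iid observation noise. With classes interleaved
#' across the tree (sister taxa frequently in different classes) and
#' Brownian noise dominating the class separation, phylogenetic whitening
#' markedly improves class separation, which is what [select_lambda()]
#' should detect; with `sigma2_bm = 0` the traits carry no phylogenetic
#' signal.
#'
#' @param tree a `time_tree`.
#' @param labels named two-class character vector over the tips.
#' @param delta class-mean separation.
#' @param sigma2_bm Brownian rate per Myr.
#' @param sigma_obs iid noise SD.
#' @param p number of trait dimensions (class signal on the first two).
#' @param seed integer seed.
#' @return n x p trait matrix with taxon-id row names.
#' @export
simulate_brownian_traits <- function(tree, labels, delta = 1,
                                     sigma2_bm = 0.3, sigma_obs = 0.1,
                                     p = 4, seed) {
  taxa <- as_phylo(tree)$tip.label
  cls <- sort(unique(labels))
  if (length(cls) != 2L) stop("labels must define exactly two classes")
  dir <- c(1, 0.5, rep(0, p - 2L))
  mu <- outer(ifelse(labels[taxa] == cls[1], -delta / 2, delta / 2), dir)
  with_seed(derive_seed(seed, 606), {
    X <- mu + matrix(stats::rnorm(length(taxa) * p, sd = sigma_obs), ncol = p)
    if (sigma2_bm > 0) {
      C <- brownian_cov(tree)$C[taxa, taxa]
      X <- X + t(chol(sigma2_bm * C)) %*%
        matrix(stats::rnorm(length(taxa) * p), ncol = p)
    }
    rownames(X) <- taxa
    X
  })
}

#' Generate a complete ground-truthed dataset
#'
#' Convenience wrapper: taxon table (training diets with the configured
#' class sizes, fossil taxa as `predict` rows with hidden true diets), time
#' tree, landmark configurations and moment arms.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `taxa` (taxon table), `tree`, `cladogram`, `fads`,
#'   `configs`, `arms`, `ground_truth`.
#' @export
synth_dataset <- function(spec) {
  n_tr <- spec$n_training
  train_labels <- rep(names(n_tr), n_tr)
  fossil_classes <- c("herbivore", "carnivore", "insectivore")
  fossil_labels <- with_seed(derive_seed(spec$seed, 505), {
    sample(fossil_classes, spec$n_fossil, replace = TRUE,
           prob = c(0.1, 0.3, 0.6))  # Mesozoic samples skew faunivorous
  })
  ids <- c(sprintf("fossil_%02d", seq_len(spec$n_fossil)),
           sprintf("extant_%02d", seq_along(train_labels)))
  labels <- stats::setNames(c(fossil_labels, train_labels), ids)
  trees <- make_tree(length(ids), spec$seed, n_fossil = spec$n_fossil,
                     fad_window = spec$fad_window, tip_labels = ids)
  jaws <- simulate_jaws(spec, trees$time_tree, labels)
  arms <- simulate_moment_arms(spec, labels)
  taxa <- data.frame(
    taxon_id = ids,
    diet_class = ifelse(grepl("^fossil", ids), "unknown", unname(labels)),
    role = ifelse(grepl("^fossil", ids), "predict", "training"),
    stringsAsFactors = FALSE)
  list(taxa = taxa, tree = trees$time_tree, cladogram = trees$cladogram,
       fads = trees$fads, configs = jaws$configs, arms = arms,
       ground_truth = jaws$ground_truth, spec = spec)
}
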