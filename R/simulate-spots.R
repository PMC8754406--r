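#' Parameters for synthetic two-channel spot fields
#'
#' Each simulated cell is a disk of \code{cellRadiusNm}; peroxisome spots
#' are uniform in the disk, each independently receiving a colocalized mRNA
#' spot with probability \code{trueColocProb} at a Gaussian-jittered offset
#' (\code{jitterSdNm} per axis, resampled until inside the mask); the
#' remaining mRNA spots (total drawn from \code{mrnaPerCell}) are uniform
#' in the disk. Count distributions are specified as
#' \code{list(dist = "poisson", lambda = , min = )} or
#' \code{list(dist = "const", value = )}.
#'
#' The \code{pex14SpotPreset} pins \code{trueColocProb} to 0.30, the
#' reported colocalization level of \emph{PEX14} mRNA with peroxisomes.
#'
#' @slot nCells positive integer; default 150.
#' @slot peroxisomesPerCell distribution spec; default Poisson(4), min 1.
#' @slot mrnaPerCell distribution spec for the total mRNA copy number;
#'   default Poisson(1), a low-copy transcript, so chance colocalization of
#'   untargeted copies stays well below the estimator's sampling error and
#'   the planted probability is recoverable.
#' @slot trueColocProb real in [0, 1]; default 0.30.
#' @slot jitterSdNm non-negative real; default 50.
#' @slot cellRadiusNm positive real; default 2500.
#' @slot seed integer RNG seed; must be set.
#' @export
setClass("SpotSimParams",
  representation(nCells = "integer", peroxisomesPerCell = "list",
                 mrnaPerCell = "list", trueColocProb = "numeric",
                 jitterSdNm = "numeric", cellRadiusNm = "numeric",
                 seed = "integer"),
  prototype(nCells = 150L,
            peroxisomesPerCell = list(dist = "poisson", lambda = 4, min = 1),
            mrnaPerCell = list(dist = "poisson", lambda = 1, min = 0),
            trueColocProb = 0.30, jitterSdNm = 50, cellRadiusNm = 2500,
            seed = NA_integer_),
  validity = function(object) {
    if (object@nCells < 1L) return("nCells must be >= 1")
    if (object@trueColocProb < 0 || object@trueColocProb > 1)
      return("trueColocProb must lie in [0, 1]")
    if (object@jitterSdNm < 0) return("jitterSdNm must be >= 0")
    if (object@cellRadiusNm <= 0) return("cellRadiusNm must be positive")
    for (s in c("peroxisomesPerCell", "mrnaPerCell")) {
      d <- slot(object, s)
      if (is.null(d$dist) || !d$dist %in% c("poisson", "const"))
        return(sprintf("%s$dist must be 'poisson' or 'const'", s))
    }
    TRUE
  })

#' @rdname SpotSimParams-class
#' @param ... slot values overriding the defaults.
#' @return A \code{SpotSimParams} object.
#' @export
SpotSimParams <- function(...) {
  args <- list(...)
  for (s in c("nCells", "seed"))
    if (!is.null(args[[s]])) args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list("SpotSimParams"), args))
}

#' @rdname SpotSimParams-class
#' @export
pex14SpotPreset <- function(...) SpotSimParams(trueColocProb = 0.30, ...)

.drawCount <- function(spec) {
  v <- switch(spec$dist,
              poisson = stats::rpois(1, spec$lambda),
              const = spec$value)
  max(v, spec$min %||% 0)
}

.uniformInDisk <- function(n, center, radius) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

#' Generate synthetic two-channel spot fields with known ground truth
#'
#' @param params a \linkS4class{SpotSimParams} with \code{seed} set.
#' @return List: \code{fields} (list of \linkS4class{SpotField}),
#'   \code{truth} (data.frame with per-field peroxisome/mRNA counts and the
#'   number of truly colocalized peroxisomes) and \code{params}. When
#'   \code{jitterSdNm} is large enough that jittered partners routinely
#'   exceed a typical colocalization threshold, a warning is recorded in
#'   the \code{warning} element.
#' @export
generateSpotFields <- function(params) {
  stopifnot(is(params, "SpotSimParams"))
  validObject(params)
  if (is.na(params@seed)) stop("params@seed must be set")
  set.seed(params@seed)
  R <- params@cellRadiusNm
  center <- c(0, 0)
  mask <- list(type = "disk", center = center, radius = R)
  fields <- vector("list", params@nCells)
  truth <- data.frame(field_id = character(params@nCells),
                      n_peroxisomes = integer(params@nCells),
                      n_mrna = integer(params@nCells),
                      n_true_coloc = integer(params@nCells),
                      stringsAsFactors = FALSE)
  for (i in seq_len(params@nCells)) {
    nP <- .drawCount(params@peroxisomesPerCell)
    perox <- .uniformInDisk(nP, center, R)
    coloc <- stats::runif(nP) < params@trueColocProb
    partners <- matrix(numeric(0), ncol = 2)
    for (j in which(coloc)) {
      repeat {
        p <- perox[j, ] + stats::rnorm(2, 0, params@jitterSdNm)
        if (sum((p - center)^2) <= R^2) break
      }
      partners <- rbind(partners, p)
    }
    nTotal <- .drawCount(params@mrnaPerCell)
    nExtra <- max(0L, nTotal - sum(coloc))
    extra <- .uniformInDisk(nExtra, center, R)
    fields[[i]] <- SpotField(perox, rbind(partners, extra), mask,
                             fieldId = sprintf("cell%03d", i))
    truth$field_id[i] <- sprintf("cell%03d", i)
    truth$n_peroxisomes[i] <- nP
    truth$n_mrna[i] <- nrow(partners) + nExtra
    truth$n_true_coloc[i] <- sum(coloc)
  }
  out <- list(fields = fields, truth = truth, params = params)
  if (params@jitterSdNm > 100)
    out$warning <- paste("jitterSdNm is large relative to typical",
                         "colocalization thresholds; planted truth may be",
                         "unrecoverable")
  out
}
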