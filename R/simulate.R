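#' @include AllClasses.R
NULL

#' Circular direction-tuning response
#'
#' Evaluates the two-lobed von Mises tuning curve used by the synthetic
#' generator. The curve is a weighted sum of a von Mises lobe at the preferred
#' direction and one at the opposite direction,
#' \deqn{r(\theta) = A\,[\alpha u(\theta) + \beta u(\theta - 180)],\quad
#'       u(\theta) = e^{\kappa(\cos(\theta - \theta_p) - 1)},}
#' with \eqn{\alpha, \beta} solved so that exactly
#' \eqn{r(\theta_p) = A} and \eqn{r(\theta_p + 180) = d\,A}
#' (\eqn{d} = \code{dsiFactor}). The response at \eqn{\theta_p \pm 90}
#' decreases with the concentration \eqn{\kappa}; \eqn{\kappa = 0} gives a
#' flat (untuned) curve of height \eqn{A}.
#'
#' @param direction stimulus direction(s) in degrees.
#' @param prefDirection preferred direction in degrees.
#' @param tuningWidth von Mises concentration \eqn{\kappa \ge 0}.
#' @param amplitude peak response \eqn{A \ge 0}.
#' @param dsiFactor ratio of the null (opposite) to preferred response,
#'   in `[0, 1]`.
#' @return Response amplitude(s), same length as \code{direction}.
#' @export
#' @examples
#' makeTuningResponse(c(0, 90, 180), 0, 2, 0.3, dsiFactor = 0.25)
makeTuningResponse <- function(direction, prefDirection, tuningWidth,
                               amplitude, dsiFactor) {
  stopifnot(tuningWidth >= 0, amplitude >= 0,
            dsiFactor >= 0, dsiFactor <= 1)
  if (tuningWidth < 1e-8) return(rep(amplitude, length(direction)))
  rad <- (direction - prefDirection) * pi / 180
  q <- exp(-2 * tuningWidth)
  u <- exp(tuningWidth * (cos(rad) - 1))
  u180 <- exp(tuningWidth * (cos(rad - pi) - 1))
  al <- (1 - dsiFactor * q) / (1 - q^2)
  be <- (dsiFactor - q) / (1 - q^2)
  amplitude * (al * u + be * u180)
}

## per-neuron responses of a model to one direction/tf condition
.modelTuning <- function(model, direction, tfIndex = 1L) {
  n <- model@nNeurons
  r <- vapply(seq_len(n), function(i)
    makeTuningResponse(direction, model@prefDirection[i],
                       model@tuningWidth[i], model@tuningAmplitude[i],
                       model@dsiFactor[i]), numeric(1))
  r * model@tfProfile[tfIndex]
}

#' Construct a PopulationModel
#'
#' @param nNeurons population size.
#' @param classMeans matrix (classes x neurons) of mean calcium-event
#'   amplitudes (peak \eqn{\Delta F/F} of one event); rownames must name the
#'   classes (see \code{\link{stimulusClasses}}).
#' @param baselineF baseline fluorescence (a.u.), recycled per neuron.
#' @param prefDirection,tuningWidth,tuningAmplitude,dsiFactor per-neuron
#'   tuning parameters, recycled.
#' @param tfProfile multiplicative gain per temporal frequency (length 5).
#' @param noiseSd private trial noise SD, recycled.
#' @param sharedGainSd SD of the rank-1 shared gain (0 = no noise
#'   correlations).
#' @param gainLoadings per-neuron loadings on the shared gain, recycled.
#' @param measurementSd additive fluorescence noise SD (a.u.).
#' @param calciumTau calcium decay time constant (s).
#' @param blockS shared-gain block duration (s).
#' @param eventRate per-neuron calcium-event rate within class epochs (Hz).
#' @return A \linkS4class{PopulationModel}.
#' @export
#' @examples
#' m <- populationModel(4, matrix(1, 6, 4,
#'        dimnames = list(stimulusClasses(), NULL)))
populationModel <- function(nNeurons, classMeans, baselineF = 100,
                            prefDirection = 0, tuningWidth = 2,
                            tuningAmplitude = 0, dsiFactor = 0.3,
                            tfProfile = rep(1, 5), noiseSd = 0.1,
                            sharedGainSd = 0, gainLoadings = 1,
                            measurementSd = 1, calciumTau = 0.5,
                            blockS = 1, eventRate = 0.5) {
  n <- as.integer(nNeurons)
  classMeans <- as.matrix(classMeans)
  tfProfile <- as.numeric(tfProfile)
  names(tfProfile) <- as.character(gratingTemporalFrequencies())
  new("PopulationModel", nNeurons = n,
      baselineF = rep_len(baselineF, n), classMeans = classMeans,
      prefDirection = rep_len(prefDirection, n) %% 360,
      tuningWidth = rep_len(tuningWidth, n),
      tuningAmplitude = rep_len(tuningAmplitude, n),
      dsiFactor = rep_len(dsiFactor, n), tfProfile = tfProfile,
      noiseSd = rep_len(noiseSd, n), sharedGainSd = sharedGainSd,
      gainLoadings = rep_len(gainLoadings, n),
      measurementSd = measurementSd, calciumTau = calciumTau, blockS = blockS,
      eventRate = rep_len(eventRate, n))
}

#' Convenience population models
#'
#' \code{tunedPopulationModel()} draws class-specific mean-response signatures
#' and direction tuning at random, giving a decodable population.
#' \code{labelIndependentModel()} uses identical class means for every class
#' and zero tuning amplitude, so stimulus labels carry no information and any
#' decoder must perform at chance; trial-to-trial variability comes from the
#' private noise (and shared gain, if enabled).
#'
#' @param nNeurons population size.
#' @param seed integer seed for the random model parameters.
#' @param baseMean mean response amplitude common to all classes.
#' @param classSeparation SD of the class-specific amplitude signatures; 0
#'   makes classes indistinguishable.
#' @param tuningAmplitude peak direction-tuning response.
#' @param noiseSd private trial noise SD.
#' @param sharedGainSd shared-gain SD (noise correlations).
#' @param ... further arguments passed to \code{\link{populationModel}}.
#' @return A \linkS4class{PopulationModel}.
#' @export
#' @examples
#' m <- tunedPopulationModel(8, seed = 1)
#' mL <- labelIndependentModel(8)
tunedPopulationModel <- function(nNeurons, seed = 1, baseMean = 2,
                                 classSeparation = 0.5,
                                 tuningAmplitude = 0.3, noiseSd = 0.1,
                                 sharedGainSd = 0, ...) {
  cls <- stimulusClasses()
  withr::with_seed(seed, {
    cm <- matrix(pmax(0, baseMean + classSeparation *
                        stats::rnorm(length(cls) * nNeurons)),
                 length(cls), nNeurons, dimnames = list(cls, NULL))
    cm["spontaneous", ] <- pmax(0, baseMean / 2 +
                                  classSeparation / 2 * stats::rnorm(nNeurons))
    pref <- stats::runif(nNeurons, 0, 360)
    width <- stats::runif(nNeurons, 1, 4)
    dsi <- stats::runif(nNeurons, 0.1, 0.9)
  })
  populationModel(nNeurons, cm, prefDirection = pref, tuningWidth = width,
                  tuningAmplitude = tuningAmplitude, dsiFactor = dsi,
                  noiseSd = noiseSd, sharedGainSd = sharedGainSd, ...)
}

#' @rdname tunedPopulationModel
#' @export
labelIndependentModel <- function(nNeurons, baseMean = 2, noiseSd = 0.1,
                                  sharedGainSd = 0, ...) {
  cls <- stimulusClasses()
  cm <- matrix(baseMean, length(cls), nNeurons, dimnames = list(cls, NULL))
  populationModel(nNeurons, cm, tuningAmplitude = 0, noiseSd = noiseSd,
                  sharedGainSd = sharedGainSd, ...)
}

#' Session plans
#'
#' \code{gratingPlan()} describes the drifting-grating block: 8 directions x
#' 5 temporal frequencies x \code{nRepeats} trials in randomized order, each
#' 2 s of grating followed by 1 s of mean-luminance gray.
#' \code{sessionSpec()} builds one session; \code{defaultSessionSpecs()}
#' returns the three-session plan (A: drifting gratings + natural movies +
#' spontaneous; B: static gratings, natural images, natural movies,
#' spontaneous; C: noise, natural movies, spontaneous) with equal total
#' duration (1800 s) per stimulus class, so 6-class chance is exactly 1/6.
#'
#' @param nRepeats trials per (direction, temporal frequency) condition.
#' @param durationOn,durationGray grating-on and gray durations (s).
#' @param directions,temporalFrequencies condition sets.
#' @return \code{gratingPlan()}: a list; \code{sessionSpec()}: a
#'   \linkS4class{SessionSpec}; \code{defaultSessionSpecs()}: a named list of
#'   three \linkS4class{SessionSpec}s.
#' @export
#' @examples
#' defaultSessionSpecs()[["A"]]
gratingPlan <- function(nRepeats = 15, durationOn = 2, durationGray = 1,
                        directions = gratingDirections(),
                        temporalFrequencies = gratingTemporalFrequencies()) {
  list(nRepeats = as.integer(nRepeats), durationOn = durationOn,
       durationGray = durationGray, directions = directions,
       temporalFrequencies = temporalFrequencies)
}

#' @rdname gratingPlan
#' @param sessionId session label.
#' @param epochPlan data.frame with columns \code{class}, \code{duration_s}.
#' @param gratingPlan list from \code{gratingPlan()}, or \code{list()} for
#'   none; the grating epoch precedes the epochs of \code{epochPlan}.
#' @param frameRate acquisition rate (Hz).
#' @export
sessionSpec <- function(sessionId, epochPlan,
                        gratingPlan = list(), frameRate = 30) {
  new("SessionSpec", sessionId = as.character(sessionId),
      epochPlan = as.data.frame(epochPlan), gratingPlan = gratingPlan,
      frameRate = frameRate)
}

#' @rdname gratingPlan
#' @param frameRate acquisition rate (Hz).
#' @export
defaultSessionSpecs <- function(frameRate = 30) {
  ep <- function(class, dur) data.frame(class = class, duration_s = dur)
  list(
    A = sessionSpec("A",
          ep(c("natural_movies", "spontaneous"), c(600, 600)),
          gratingPlan = gratingPlan(), frameRate = frameRate),
    B = sessionSpec("B",
          ep(c("static_gratings", "natural_images",
               "natural_movies", "spontaneous"), c(1800, 1800, 600, 600)),
          frameRate = frameRate),
    C = sessionSpec("C",
          ep(c("noise", "natural_movies", "spontaneous"),
             c(1800, 600, 600)), frameRate = frameRate))
}

#' @rdname gratingPlan
#' @param classDuration total duration (s) per stimulus class across the
#'   three sessions; 1000 s per class yields 600 ten-second samples in total.
#' @details \code{balancedSessionSpecs()} builds a three-session plan with
#' stationary epochs only (no grating trial structure) and exactly equal total
#' duration per class — the layout used for chance-level calibration of the
#' stimulus-class decoder.
#' @export
balancedSessionSpecs <- function(classDuration = 1000, frameRate = 30) {
  cd <- classDuration
  ep <- function(class, dur) data.frame(class = class, duration_s = dur)
  list(
    A = sessionSpec("A", ep(c("drifting_gratings", "natural_movies",
                              "spontaneous"), cd * c(1, 0.34, 0.32)),
                    frameRate = frameRate),
    B = sessionSpec("B", ep(c("static_gratings", "natural_images",
                              "natural_movies", "spontaneous"),
                            cd * c(1, 1, 0.33, 0.34)),
                    frameRate = frameRate),
    C = sessionSpec("C", ep(c("noise", "natural_movies", "spontaneous"),
                            cd * c(1, 0.33, 0.34)), frameRate = frameRate))
}

## randomized trial table for a grating plan; assumes RNG is already seeded
.makeTrialTable <- function(gp, startS) {
  conds <- expand.grid(direction_deg = gp$directions,
                       temporal_freq_hz = gp$temporalFrequencies)
  conds <- conds[rep(seq_len(nrow(conds)), gp$nRepeats), ]
  conds <- conds[sample.int(nrow(conds)), ]
  per <- gp$durationOn + gp$durationGray
  data.frame(onset_s = startS + (seq_len(nrow(conds)) - 1) * per,
             duration_s = gp$durationOn,
             direction_deg = conds$direction_deg,
             temporal_freq_hz = conds$temporal_freq_hz,
             row.names = NULL)
}

#' Simulate a calcium-imaging session
#'
#' Generates a fluorescence recording plus its stimulus tables from a
#' population model and a session plan. Latent activity has two components:
#' \itemize{
#'   \item \emph{Calcium events} within stimulus-class epochs: each neuron
#'     emits events as a Poisson process (\code{eventRate}); each event is a
#'     transient with peak amplitude \code{classMeans[class, i]} times an
#'     exponential variate, scaled by \code{(1 + loading x shared gain)} —
#'     the shared gain is redrawn every \code{blockS} seconds, which induces
#'     noise correlations — and clipped at 0. During a grating epoch the
#'     background events use the spontaneous class amplitudes.
#'   \item \emph{Sustained grating responses}: during each 2-s trial the
#'     direction-tuning response (times the temporal-frequency gain) scaled by
#'     \code{(1 + shared gain)} plus private Gaussian noise, clipped at 0, is
#'     added as a sustained amplitude; the 1-s gray periods carry background
#'     events only.
#' }
#' The activity is passed through a single-exponential calcium kernel (time
#' constant \code{calciumTau}) and converted to fluorescence
#' \eqn{F = F_{base}(1 + \mathrm{activity}) + \varepsilon} with white
#' measurement noise. Deterministic given \code{seed}.
#'
#' @param model a \linkS4class{PopulationModel}.
#' @param spec a \linkS4class{SessionSpec}.
#' @param seed integer seed.
#' @return List with elements \code{recording}
#'   (\linkS4class{FluorescenceRecording}), \code{epochs} (data.frame
#'   \code{start_s}, \code{stop_s}, \code{class}) and \code{trials}
#'   (data.frame \code{onset_s}, \code{duration_s}, \code{direction_deg},
#'   \code{temporal_freq_hz}; \code{NULL} without a grating plan).
#' @export
#' @examples
#' m <- labelIndependentModel(4)
#' s <- sessionSpec("B", data.frame(class = "spontaneous", duration_s = 30))
#' sim <- simulateRecording(m, s, seed = 1)
#' sim$recording
simulateRecording <- function(model, spec, seed = 1) {
  stopifnot(is(model, "PopulationModel"), is(spec, "SessionSpec"))
  validObject(model); validObject(spec)
  rate <- spec@frameRate
  gp <- spec@gratingPlan
  nN <- model@nNeurons

  withr::with_seed(as.integer(seed), {
    ## session layout --------------------------------------------------------
    trials <- NULL
    gDur <- 0
    if (length(gp)) {
      trials <- .makeTrialTable(gp, 0)
      gDur <- nrow(trials) * (gp$durationOn + gp$durationGray)
    }
    ep <- spec@epochPlan
    bad <- setdiff(ep$class, rownames(model@classMeans))
    if (length(bad))
      stop("no class means for epoch class(es): ", paste(bad, collapse = ", "))
    durs <- c(if (gDur > 0) gDur, ep$duration_s)
    clss <- c(if (gDur > 0) "drifting_gratings", ep$class)
    if (!length(durs)) stop("session plan is empty")
    stops <- cumsum(durs)
    epochs <- data.frame(start_s = c(0, stops[-length(stops)]),
                         stop_s = stops, class = clss)
    totalDur <- stops[length(stops)]
    nFrames <- round(totalDur * rate)
    ts <- (seq_len(nFrames) - 1) / rate

    ## shared gain: one latent value per block, common to all neurons --------
    zBlocks <- stats::rnorm(ceiling(totalDur / model@blockS) + 1L, 0,
                            model@sharedGainSd)
    zAt <- function(t) zBlocks[floor(t / model@blockS) + 1L]

    lambda <- if (model@calciumTau > 0) exp(-1 / (model@calciumTau * rate))
              else 0
    activity <- matrix(0, nN, nFrames)   # filter input

    ## calcium events within each epoch (grating epoch: spontaneous bkg) -----
    addEvents <- function(start, stop, amps) {
      dur <- stop - start
      for (i in seq_len(nN)) {
        nEv <- stats::rpois(1L, model@eventRate[i] * dur)
        if (nEv == 0L) next
        tEv <- start + stats::runif(nEv, 0, dur)
        a <- pmax(0, amps[i] * stats::rexp(nEv) *
                    (1 + model@gainLoadings[i] * zAt(tEv)))
        fr <- pmin(nFrames, floor(tEv * rate) + 1L)
        impulse <- a / (1 - lambda)
        for (k in seq_len(nEv))
          activity[i, fr[k]] <- activity[i, fr[k]] + impulse[k]
      }
      activity
    }
    for (k in seq_len(nrow(epochs))) {
      cls <- if (epochs$class[k] == "drifting_gratings" && gDur > 0 &&
                 epochs$start_s[k] == 0) "spontaneous" else epochs$class[k]
      activity <- addEvents(epochs$start_s[k], epochs$stop_s[k],
                            model@classMeans[cls, ])
    }

    ## sustained tuned responses during grating trials -----------------------
    if (!is.null(trials)) {
      tfLevels <- gp$temporalFrequencies
      for (k in seq_len(nrow(trials))) {
        on <- trials$onset_s[k]
        mu <- .modelTuning(model, trials$direction_deg[k],
                           match(trials$temporal_freq_hz[k], tfLevels))
        amp <- pmax(0, mu * (1 + model@gainLoadings * zAt(on)) +
                      stats::rnorm(nN, 0, model@noiseSd))
        i0 <- floor(on * rate + 1e-9) + 1L
        i1 <- min(nFrames, ceiling((on + gp$durationOn) * rate - 1e-9))
        if (i1 >= i0) activity[, i0:i1] <- activity[, i0:i1] + amp
      }
    }

    if (lambda > 0)
      activity <- t(apply(activity * (1 - lambda), 1, function(a)
        as.numeric(stats::filter(a, lambda, method = "recursive"))))

    flo <- model@baselineF * (1 + activity)
    if (model@measurementSd > 0)
      flo <- flo + matrix(stats::rnorm(length(flo), 0, model@measurementSd),
                          nrow(flo), ncol(flo))
    flo[flo < 0] <- 0
    rec <- fluorescenceRecording(flo, ts,
                                 paste0("neuron_", seq_len(nN)),
                                 sessionId = spec@sessionId,
                                 frameRate = rate)
  })
  list(recording = rec, epochs = epochs, trials = trials)
}

#' Noise-free or noisy latent trial responses to a grating plan
#'
#' Bypasses the calcium/fluorescence stage and returns the latent per-trial
#' population response amplitudes directly as a \linkS4class{FeatureDataset}
#' (one sample per grating trial, labeled by direction, with
#' \code{direction_deg} and \code{temporal_freq_hz} metadata). With
#' \code{noise = FALSE} the responses equal the tuning curve exactly, which is
#' the reference path for validating selectivity indices against their
#' closed-form values.
#'
#' @param model a \linkS4class{PopulationModel}.
#' @param plan a grating plan (see \code{\link{gratingPlan}}).
#' @param seed integer seed (trial order; and noise when enabled).
#' @param noise if \code{FALSE}, suppress shared-gain and private noise.
#' @return A \linkS4class{FeatureDataset} (unnormalized).
#' @export
#' @examples
#' fd <- simulateTrialResponses(tunedPopulationModel(4), gratingPlan(2))
simulateTrialResponses <- function(model, plan = gratingPlan(), seed = 1,
                                   noise = TRUE) {
  stopifnot(is(model, "PopulationModel"))
  withr::with_seed(as.integer(seed), {
    trials <- .makeTrialTable(plan, 0)
    tfLevels <- plan$temporalFrequencies
    feats <- vapply(seq_len(nrow(trials)), function(k) {
      mu <- .modelTuning(model, trials$direction_deg[k],
                         match(trials$temporal_freq_hz[k], tfLevels))
      if (!noise) return(mu)
      z <- stats::rnorm(1, 0, model@sharedGainSd)
      pmax(0, mu * (1 + model@gainLoadings * z) +
             stats::rnorm(model@nNeurons, 0, model@noiseSd))
    }, numeric(model@nNeurons))
  })
  feats <- matrix(feats, nrow = model@nNeurons)
  featureDataset(feats, labels = as.character(trials$direction_deg),
                 neuronIds = paste0("neuron_", seq_len(model@nNeurons)),
                 windows = cbind(trials$onset_s,
                                 trials$onset_s + trials$duration_s),
                 colData = list(direction_deg = trials$direction_deg,
                                temporal_freq_hz = trials$temporal_freq_hz))
}
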