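#' The 65 Binder semantic feature names
#'
#' The experience-based semantic dimensions of the Binder conceptual
#' feature norms, in their conventional order. Every item (noun) in the
#' Demonstrative Choice Task carries a rating on each dimension, and every
#' per-subject semantic profile has exactly one value per dimension.
#'
#' @return Character vector of length 65.
#' @export
#' @examples
#' length(binder_feature_names())
binder_feature_names <- function() {
  c("Vision", "Bright", "Dark", "Color", "Pattern", "Large", "Small",
    "Motion", "Biomotion", "Fast", "Slow", "Shape", "Complexity",
    "Face", "Body", "Touch", "Temperature", "Texture", "Weight",
    "Pain", "Audition", "Loud", "Low", "High", "Sound", "Music",
    "Speech", "Taste", "Smell", "Head", "UpperLimb", "LowerLimb",
    "Practice", "Landmark", "Path", "Scene", "Near", "Toward", "Away",
    "Number", "Time", "Duration", "Long", "Short", "Caused",
    "Consequential", "Social", "Human", "Communication", "Self",
    "Cognition", "Benefit", "Harm", "Pleasant", "Unpleasant", "Happy",
    "Sad", "Angry", "Disgusted", "Fearful", "Surprised", "Drive",
    "Needs", "Attention", "Arousal")
}

#' Emotion-domain features with their valence loadings
#'
#' The affect-related Binder dimensions are strongly intercorrelated across
#' words: negatively valenced concepts score high on Unpleasant, Sad,
#' Fearful, Pain (and friends) together, and low on Pleasant, Happy,
#' Benefit. The synthetic Binder generator reproduces this by loading the
#' block on a shared latent valence factor with these signs.
#'
#' @return Named numeric vector: +1 for negative-affect features, -1 for
#'   positive-affect features.
#' @export
emotion_block_loadings <- function() {
  c(Unpleasant = 1, Sad = 1, Angry = 1, Disgusted = 1, Fearful = 1,
    Pain = 1, Harm = 1,
    Pleasant = -1, Happy = -1, Benefit = -1)
}

#' Default planted group-effect template
#'
#' Log-odds weights of each Binder feature on proximal demonstrative
#' choice, by group. The depression template weights the negative-affect
#' features positively (more proximal choices for sad/fearful/unpleasant/
#' painful/disgusting concepts) and the positive-affect features
#' negatively, the direction reported for depression in DCT studies; the
#' control template is flat.
#'
#' @param weight Magnitude of each planted weight (log-odds per SD of the
#'   feature score). Default 0.5.
#' @return A list with numeric 65-vectors `beta_dep` and `beta_ctrl`,
#'   named by feature.
#' @export
default_effect_template <- function(weight = 0.5) {
  feats <- binder_feature_names()
  beta_dep <- setNames(numeric(65), feats)
  beta_dep[c("Sad", "Fearful", "Unpleasant", "Pain", "Disgusted")] <- weight
  beta_dep[c("Happy", "Pleasant", "Benefit", "Drive", "LowerLimb")] <- -weight
  beta_ctrl <- setNames(numeric(65), feats)
  list(beta_dep = beta_dep, beta_ctrl = beta_ctrl)
}
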