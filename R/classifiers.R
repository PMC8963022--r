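# Pluggable classifier contract: a classifier is a list with a `name`, a
# `fit(X, y, rng)` returning a model object, and a `predict(model, X)`
# returning a factor/character of class names. Stochastic fits draw only
# through the supplied rng handle, so experiments are reproducible.

#' Classifier constructors for the evaluation harness
#'
#' The roster used to compare sampling strategies: k-nearest neighbours,
#' multinomial logistic regression, an RBF support vector machine, a random
#' forest (all at their library defaults) and a multilayer perceptron with
#' one hidden layer of 100 ReLU units trained with Adam on the softmax
#' cross-entropy loss (learning rate 0.001, L2 penalty 1e-4, up to 200
#' epochs, minibatch `min(200, n)`, stopping early after 10 epochs without a
#' 1e-4 loss improvement).
#'
#' @param k neighbours for `classifier_knn`.
#' @return a classifier object usable by [run_experiment()].
#' @name classifiers
NULL

#' @rdname classifiers
#' @export
classifier_knn <- function(k = 5L) {
  list(
    name = "KNN",
    fit = function(X, y, rng) list(X = X, y = y, k = k),
    predict = function(model, X) {
      as.character(class::knn(model$X, X, factor(model$y), k = model$k))
    }
  )
}

#' @rdname classifiers
#' @export
classifier_lr <- function() {
  list(
    name = "LR",
    fit = function(X, y, rng) {
      df <- data.frame(X)
      df$.y <- factor(y)
      with_rng(rng, nnet::multinom(.y ~ ., data = df, trace = FALSE,
                                   maxit = 200, MaxNWts = 5000))
    },
    predict = function(model, X) {
      as.character(stats::predict(model, newdata = data.frame(X)))
    }
  )
}

#' @rdname classifiers
#' @export
classifier_svm <- function() {
  list(
    name = "SVM",
    fit = function(X, y, rng) {
      with_rng(rng, e1071::svm(X, factor(y)))
    },
    predict = function(model, X) as.character(stats::predict(model, X))
  )
}

#' @rdname classifiers
#' @export
classifier_rf <- function() {
  list(
    name = "RF",
    fit = function(X, y, rng) {
      with_rng(rng, randomForest::randomForest(X, factor(y)))
    },
    predict = function(model, X) as.character(stats::predict(model, X))
  )
}

#' @rdname classifiers
#' @param hidden,learning_rate,l2,epochs,batch_size,tol,patience MLP
#'   hyperparameters (see Description for the defaults).
#' @export
classifier_mlp <- function(hidden = 100L, learning_rate = 1e-3, l2 = 1e-4,
                           epochs = 200L, batch_size = 200L, tol = 1e-4,
                           patience = 10L) {
  list(
    name = "MLP",
    fit = function(X, y, rng) {
      mlp_fit(X, factor(y), hidden = hidden, learning_rate = learning_rate,
              l2 = l2, epochs = epochs, batch_size = batch_size, tol = tol,
              patience = patience, rng = rng)
    },
    predict = function(model, X) mlp_predict(model, X)
  )
}

#' @rdname classifiers
#' @export
default_classifiers <- function() {
  list(classifier_knn(), classifier_lr(), classifier_svm(),
       classifier_rf(), classifier_mlp())
}

# --- minimal single-hidden-layer ReLU network trained with Adam ------------
# No installed R package offers this architecture/optimiser combination
# (nnet is logistic-sigmoid + BFGS), so it is implemented here directly:
# dense(d -> h) + ReLU + dense(h -> K) + softmax, minimising mean
# cross-entropy with an L2 penalty 0.5 * l2 * ||W||^2 / n_batch, minibatch
# Adam (beta1 .9, beta2 .999, eps 1e-8), Glorot-uniform initialisation.
# The training loop lives in compiled code (src/mlp_adam.cpp); weights are
# initialised and epoch shuffles drawn here from the rng handle so fits are
# bit-reproducible.

mlp_fit <- function(X, y, hidden, learning_rate, l2, epochs, batch_size,
                    tol, patience, rng) {
  X <- as.matrix(X)
  lev <- levels(y)
  n <- nrow(X); d <- ncol(X); K <- length(lev)
  glorot <- function(fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(rng_uniform(rng, fan_in * fan_out) * 2 * lim - lim,
           fan_in, fan_out)
  }
  W1 <- glorot(d, hidden); W2 <- glorot(hidden, K)
  orders <- with_rng(rng, vapply(seq_len(epochs),
                                 function(e) sample.int(n), integer(n)))
  fit <- mlp_adam_train(X, as.integer(y), K, W1, rep(0, hidden), W2,
                        rep(0, K), orders, learning_rate, l2,
                        as.integer(batch_size), tol, as.integer(patience))
  list(par = list(W1 = fit$W1, b1 = as.numeric(fit$b1), W2 = fit$W2,
                  b2 = as.numeric(fit$b2)),
       levels = lev, loss = fit$loss, epochs_run = fit$epochs_run)
}

mlp_predict <- function(model, X) {
  X <- as.matrix(X)
  H <- pmax(sweep(X %*% model$par$W1, 2L, model$par$b1, "+"), 0)
  logits <- sweep(H %*% model$par$W2, 2L, model$par$b2, "+")
  model$levels[max.col(logits, ties.method = "first")]
}
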