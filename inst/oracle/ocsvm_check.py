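"""Independent nu one-class SVM oracle (scikit-learn).

Reads JSON on stdin:
  {"train": [[...]], "test": [[...]], "nu": 0.2, "gamma": 0.5}
Fits sklearn.svm.OneClassSVM with the RBF kernel and writes JSON:
  {"train_labels": [...], "test_labels": [...],
   "train_scores": [...], "test_scores": [...]}
where labels are 1 (inlier) / -1 (outlier) and scores are the signed
decision-function values.
"""
import json
import sys

import numpy as np
from sklearn.svm import OneClassSVM


if __name__ == "__main__":
    msg = json.load(sys.stdin)
    train = np.asarray(msg["train"], dtype=float)
    test = np.asarray(msg["test"], dtype=float)
    model = OneClassSVM(kernel="rbf", nu=msg["nu"], gamma=msg["gamma"],
                        tol=1e-9)
    model.fit(train)
    json.dump(
        {
            "train_labels": model.predict(train).tolist(),
            "test_labels": model.predict(test).tolist(),
            "train_scores": model.decision_function(train).tolist(),
            "test_scores": model.decision_function(test).tolist(),
        },
        sys.stdout,
    )
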