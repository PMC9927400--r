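#ifndef RFARADIOMICS_TYPES_H
#define RFARADIOMICS_TYPES_H

#include <vector>

// Random-forest containers shared with the generated Rcpp glue.
struct Node {
  int feature = -1;      // -1 marks a leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double prob1 = 0.0;    // class-1 fraction in the node (leaf payload)
};

struct Tree {
  std::vector<Node> nodes;
};

struct Forest {
  std::vector<Tree> trees;
  std::vector<double> importance;
  int p = 0;
};

#endif
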