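#ifndef SEQSCRUB_H
#define SEQSCRUB_H

#include <string>

std::string revcomp_one(const std::string &s);

#endif
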