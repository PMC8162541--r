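#ifndef DDMLONG_WFPT_H
#define DDMLONG_WFPT_H

double wfpt_logpdf1(double t, double v, double a, double w, double eps);

#endif
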