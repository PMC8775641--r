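factor,public,work,partner,educational
Socio-economic level,0.448,-0.372,-0.483,-0.057
Educational level,0.485,0.441,-0.081,0.049
Family networks,0.426,-1.191,-0.384,-0.472
Family similar networks,-0.092,1.411,0.206,-0.517
Friend networks,0.713,0.078,-0.567,0.866
Neighborhood networks,-0.244,-0.289,-0.392,-0.518
Religious org. networks,-0.275,-0.101,0.058,0.176
Other networks,0.051,0.822,0.464,0.454
Partner educational level,-0.100,0.471,0.652,0.368
Economic dependence,0.058,0.013,0.514,-0.748
Sexual stereotypes,0.064,-0.238,-0.144,-0.597
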